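importer,exporter,entry_year
AAA,BBB,1992
DDD,EEE,1993
BBB,AAA,1994
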