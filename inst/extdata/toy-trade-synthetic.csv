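reporter,partner,year,quantity
AAA,BBB,1990,100
AAA,BBB,1991,120
AAA,BBB,1992,80
CCC,BBB,1990,50
CCC,BBB,1992,60
DDD,EEE,1991,10
DDD,EEE,1992,10
DDD,EEE,1993,10
DDD,EEE,1994,10
BBB,AAA,1992,30
BBB,AAA,1993,30
BBB,AAA,1994,30
EEE,DDD,1990,5
EEE,DDD,1991,5
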