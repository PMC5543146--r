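# Derived per-(set, replicate) seed so every replicate has its own
# reproducible stream. Kept inside 32-bit integer range.
derive_seed <- function(seed, set, rep) {
  s <- (as.double(seed) * 48271 + as.double(set) * 104729 + as.double(rep) * 7919)
  as.integer(s %% 2147483647)
}

# Accept a parameter-set data.frame (columns alpha, beta, epsilon, C, lam) or
# a list of growth_params; return a list of growth_params.
as_param_list <- function(param_sets) {
  if (inherits(param_sets, "growth_params")) return(list(param_sets))
  if (is.data.frame(param_sets)) {
    need <- c("alpha", "beta", "epsilon", "C", "lam")
    if (!all(need %in% names(param_sets))) {
      stop("parameter data.frame needs columns: ", paste(need, collapse = ", "))
    }
    return(lapply(seq_len(nrow(param_sets)), function(k) {
      growth_params(param_sets$alpha[k], param_sets$beta[k], param_sets$epsilon[k],
                    param_sets$C[k], param_sets$lam[k])
    }))
  }
  stopifnot(is.list(param_sets), all(vapply(param_sets, inherits, TRUE, "growth_params")))
  param_sets
}
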