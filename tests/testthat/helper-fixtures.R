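# Shared fixtures: tiny sequences with closed-form ensembles and the
# three shipped energy models.

seq_gaaac <- function() validate_sequence("GAAAC", "gaaac")
seq_ggaaacc <- function() validate_sequence("GGAAACC", "ggaaacc")

mod_uniform <- function() energy_model("toy-uniform")
mod_pairtype <- function() energy_model("toy-pairtype")
mod_stacking <- function() energy_model("stacking")

all_models <- function() {
  list(mod_uniform(), mod_pairtype(), mod_stacking())
}

# exact ensemble quantities for GAAAC under toy-uniform:
# two structures {open, (1,5)} with weights {1, e}
P15_UNIFORM <- exp(1) / (1 + exp(1))        # 0.7310586
P15_PAIRTYPE <- exp(3) / (1 + exp(3))       # 0.9525741
# GGAAACC under toy-uniform: Z = 1 + 4e + e^2
Z_GG <- 1 + 4 * exp(1) + exp(1)^2
P17_UNIFORM <- (exp(1) + exp(1)^2) / Z_GG   # 0.5247244
PU1_GG <- (1 + 2 * exp(1)) / Z_GG           # 0.3341555

pair_set <- function(s) {
  if (nrow(s) == 0L) return("open")
  paste(sort(paste0(s[, 1L], "-", s[, 2L])), collapse = ";")
}
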