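# shared scenarios used across test files

table1 <- function() preset_params("ecoli_table1")
threeway <- function() preset_params("lu_threeway")

# frozen regulation (r = 0): transcription fires at the constant rate K*r0
frozen_params <- function(rate = 10, B = 5, K = 50, gamma = 150, gamma0 = 1) {
  model_params(B = B, gamma = gamma, gamma0 = gamma0, r = 0, r0 = rate / K,
               K = K)
}

# deterministic high-X attractor of the Table-1 toggle (molecules),
# from find_attractors; frozen here to avoid recomputation in every file
TABLE1_ATTR <- c(x = 371.08915, y = 88.72962)
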