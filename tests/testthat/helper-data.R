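# small dataset builders shared across test files

toy_dataset <- function(n = 12, p = 3, K = 2, seed = 42) {
  set.seed(seed)
  x <- as.data.frame(matrix(runif(n * p, 0, 10), n, p))
  names(x) <- paste0("a", seq_len(p))
  hb_dataset(x, sample(paste0("class", seq_len(K)), n, replace = TRUE),
             class_names = paste0("class", seq_len(K)))
}

# a 1-D dataset whose two classes are perfectly separated
separable_1d <- function() {
  hb_dataset(data.frame(a = c(1, 2, 8, 9), b = c(5, 5, 5, 5)),
             c("lo", "lo", "hi", "hi"), class_names = c("hi", "lo"))
}

small_gen_cfg <- function(n = 120, separability = 0.85, alignment = 1,
                          seed = 7) {
  generator_config(n = n, separability = separability,
                   cluster_alignment = alignment, seed = seed)
}
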