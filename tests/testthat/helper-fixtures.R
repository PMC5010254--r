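# Shared miniature fixtures built in code.

# 90-bp circle: 45-bp gene [0,45) (ATG + 13 stop-free codons + TAG), tRNA
# wrapping the origin [81,90)+[0,3), noncoding remainder
small_circle <- function(seed = 51) {
  set.seed(seed)
  body <- paste(sample(setdiff(names(genetic_code()$map),
                               c("TAA", "TAG")), 13, replace = TRUE),
                collapse = "")
  circ <- nuc_seq(paste0("ATG", body, "TAG", random_dna(36), random_dna(9)),
                  id = "ref", topology = "circular")
  mc <- minicircle(circ)
  mc <- add_feature(mc, "gene", interval(0, 45))
  mc <- add_feature(mc, "tRNA", interval(81, 3, wraps = TRUE))
  mc
}
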