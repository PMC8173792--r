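# Hand-built miniature ASV table: 3 biological samples + 1 extraction
# control, 3 ASVs with the contamination pattern worked out by hand
# (ASV_A: 10 control reads of 60 total = 16.7% -> contaminant;
#  ASV_B: absent from control; ASV_C: 1 of 100 = 1%).
tiny_asv_table <- function() {
  counts <- rbind(
    S1 = c(ASV_A = 25L, ASV_B = 60L, ASV_C = 49L),
    S2 = c(ASV_A = 20L, ASV_B = 35L, ASV_C = 45L),
    S3 = c(ASV_A = 5L,  ASV_B = 5L,  ASV_C = 5L),
    Ctl = c(ASV_A = 10L, ASV_B = 0L, ASV_C = 1L))
  asv_table(
    counts,
    taxonomy = c(ASV_A = "d__Bacteria;p__P;c__C;o__O;f__FamA;g__GA",
                 ASV_B = "d__Bacteria;p__P;c__C;o__O;f__FamB;g__GB",
                 ASV_C = "d__Bacteria;p__P;c__C;o__O;f__FamC;g__GC"),
    sample_meta = data.frame(
      sample_id = c("S1", "S2", "S3", "Ctl"),
      treatment = c("SymL", "SymD", "ApoL", "control"),
      is_control = c(FALSE, FALSE, FALSE, TRUE)))
}

star_tree <- function(tips, branch = 1) {
  ape::read.tree(text = paste0("(", paste0(tips, ":", branch,
                                           collapse = ","), ");"))
}

# Independent PERMANOVA oracle: pseudo-F straight from the definition and
# the exact two-group permutation distribution by full enumeration of
# group-1 index sets.
oracle_pseudo_f <- function(dmat, labels) {
  n <- nrow(dmat)
  a <- length(unique(labels))
  sst <- sum(dmat^2) / (2 * n)
  ssw <- 0
  for (g in unique(labels)) {
    i <- which(labels == g)
    ssw <- ssw + sum(dmat[i, i]^2) / (2 * length(i))
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

oracle_exhaustive_p <- function(dmat, labels) {
  stopifnot(length(unique(labels)) == 2)
  n <- nrow(dmat)
  n1 <- sum(labels == unique(labels)[1])
  f_obs <- oracle_pseudo_f(dmat, labels)
  sets <- utils::combn(n, n1, simplify = FALSE)
  f_all <- vapply(sets, function(a) {
    lab <- rep("g2", n)
    lab[a] <- "g1"
    oracle_pseudo_f(dmat, lab)
  }, numeric(1))
  mean(f_all >= f_obs - 1e-12)
}
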