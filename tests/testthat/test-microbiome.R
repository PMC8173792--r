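test_that("contamination filter applies the 10% control-occurrence rule", {
  tab <- tiny_asv_table()
  res <- filter_contaminants(tab)
  # ASV_A: 10/60 = 16.7% in the control -> removed; others kept
  expect_equal(res$removed$asv_id, "ASV_A")
  expect_equal(res$removed$control_fraction, 10 / 60, tolerance = 1e-12)
  expect_false(res$removed$control_only)
  expect_equal(colnames(res$table$counts), c("ASV_B", "ASV_C"))
  # control sample dropped from the output
  expect_false(any(res$table$sample_meta$is_control))
  # all-zero control removes nothing
  tab0 <- tab
  tab0$counts["Ctl", ] <- 0L
  expect_equal(nrow(filter_contaminants(tab0)$removed), 0)
  # no control flagged is a configuration error
  tabnc <- tab
  tabnc$sample_meta$is_control <- FALSE
  expect_error(filter_contaminants(tabnc), "control")
})

test_that("the filter never removes an ASV absent from the control", {
  set.seed(3)
  for (i in 1:20) {
    counts <- matrix(rpois(40, 20), nrow = 4,
                     dimnames = list(c("a", "b", "c", "ctl"),
                                     paste0("v", 1:10)))
    counts["ctl", sample(10, 5)] <- 0L
    tab <- asv_table(counts, setNames(rep("t", 10), paste0("v", 1:10)),
                     data.frame(sample_id = c("a", "b", "c", "ctl"),
                                treatment = c("SymL", "SymD", "ApoL",
                                              "control"),
                                is_control = c(FALSE, FALSE, FALSE, TRUE)))
    res <- filter_contaminants(tab, threshold = 0.05)
    expect_true(all(counts["ctl", res$removed$asv_id] > 0))
  }
})

test_that("samples-only denominator is available for the ambiguous reading", {
  tab <- tiny_asv_table()
  res <- filter_contaminants(tab, include_control_in_total = FALSE)
  # ASV_A: 10/50 = 20% of biological reads
  expect_equal(res$removed$control_fraction[res$removed$asv_id == "ASV_A"],
               10 / 50)
})

test_that("relative abundances sum to one per sample", {
  tab <- tiny_asv_table()
  rel <- relative_abundance(tab)
  expect_equal(unname(rowSums(rel)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(relative_abundance(matrix(c(85, 10, 5), 1,
                                                dimnames = list("s", NULL)))[1, ]),
               c(0.85, 0.10, 0.05))
  m <- tab$counts
  m["S1", ] <- 0L
  expect_error(relative_abundance(m), "zero reads")
})

test_that("family composition keeps top families and pools the rest", {
  tab <- tiny_asv_table()
  fam <- family_composition(filter_contaminants(tab)$table, top_k = 1)
  expect_equal(sort(colnames(fam)), sort(c("FamC", "others")))
  expect_equal(unname(rowSums(fam)), rep(1, 3), tolerance = 1e-12)
  # single-family table: that family is 1, others 0
  one <- filter_contaminants(tab)$table
  fam2 <- family_composition(one, top_k = 8)
  expect_equal(unname(rowSums(fam2[, c("FamB", "FamC")])), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(unname(fam2[, "others"]), rep(0, 3))
})

test_that("taxonomy ranks parse SILVA-style lineages", {
  tx <- c("d__Bacteria;p__Proteobacteria;c__Gamma;o__Pseudomonadales;f__Moraxellaceae;g__Acinetobacter",
          "d__Bacteria;p__Proteobacteria",
          "d__Bacteria;p__P;c__C;o__O;f__;g__G")
  expect_equal(taxonomy_rank(tx, "family"),
               c("Moraxellaceae", "unclassified", "unclassified"))
  expect_equal(taxonomy_rank(tx, "phylum")[1], "Proteobacteria")
})

test_that("core, symbiome and apobiome sets honour membership definitions", {
  tab <- filter_contaminants(tiny_asv_table())$table
  sets <- core_sets(tab, sym_treatments = c("SymL", "SymD"),
                    apo_treatments = "ApoL")
  # both remaining ASVs occur in every sample
  expect_setequal(sets$core, c("ASV_B", "ASV_C"))
  expect_true(all(sets$core %in% sets$symbiome))
  expect_true(all(sets$core %in% sets$apobiome))
  # zeroing ASV_B in the ApoL sample drops it from core and apobiome only
  tab$counts["S3", "ASV_B"] <- 0L
  sets2 <- core_sets(tab)
  expect_equal(sets2$core, "ASV_C")
  expect_setequal(sets2$symbiome, c("ASV_B", "ASV_C"))
  expect_equal(sets2$apobiome, "ASV_C")
})

test_that("ASV tables round-trip through TSV", {
  tab <- tiny_asv_table()
  cpath <- tempfile(fileext = ".tsv")
  mpath <- tempfile(fileext = ".tsv")
  write_asv_table(tab, cpath, mpath)
  back <- read_asv_table(cpath, mpath)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$taxonomy, tab$taxonomy)
  expect_equal(back$sample_meta$treatment, tab$sample_meta$treatment)
})

test_that("malformed inputs produce structured errors naming the problem", {
  tab <- tiny_asv_table()
  cpath <- tempfile(fileext = ".tsv")
  mpath <- tempfile(fileext = ".tsv")
  write_asv_table(tab, cpath, mpath)
  meta <- utils::read.delim(mpath)
  write_tsv_path <- tempfile(fileext = ".tsv")
  utils::write.table(meta[, c("sample_id", "is_control")], write_tsv_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_asv_table(cpath, write_tsv_path), "treatment")
  expect_error(read_delim_auto(file.path(tempdir(), "nope.tsv")),
               "not found")
})
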