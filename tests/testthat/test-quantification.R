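test_that("marker fractions equal brute-force counting", {
  tab <- data.frame(
    roi = "mPOA", animal = rep(c("a1", "a2"), each = 10),
    section = 1, hemisphere = "L",
    dapi = TRUE,
    gal = rep(c(TRUE, FALSE), 10),
    cfos = c(rep(c(TRUE, FALSE), 5), rep(FALSE, 10)))
  mf <- marker_fractions(tab, "mPOA", per_animal = FALSE)
  expect_equal(mf$frac_cfos_in_gal, sum(tab$cfos & tab$gal) / sum(tab$gal))
  expect_equal(mf$frac_gal_per_dapi, sum(tab$gal) / nrow(tab))
  # per-animal-first equals pooled when images are balanced
  mfa <- marker_fractions(tab, "mPOA", per_animal = TRUE)
  expect_equal(mfa$frac_gal_per_dapi, mf$frac_gal_per_dapi)
  expect_error(marker_fractions(tab, "vBNST"), "not present")
  # zero Gal+ cells flag the undefined fraction
  tab0 <- transform(tab, gal = FALSE, cfos = FALSE)
  mf0 <- marker_fractions(tab0, "mPOA", per_animal = FALSE)
  expect_true(mf0$no_gal)
  expect_true(is.na(mf0$frac_cfos_in_gal))
})

test_that("generated tables recover marker probabilities within 3 SE", {
  cfg <- sim_config(seed = 18, n_cells = 10000L, p_gal = 0.2,
                    p_cfos = 0.45)
  tab <- gen_cell_table(cfg, n_animals = 1L)
  mf <- marker_fractions(tab, "mPOA", per_animal = FALSE)
  n <- sum(tab$roi == "mPOA")
  expect_lt(abs(mf$frac_gal_per_dapi - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  n_gal <- sum(tab$gal[tab$roi == "mPOA"])
  expect_lt(abs(mf$frac_cfos_in_gal - 0.45),
            3 * sqrt(0.45 * 0.55 / n_gal))
  # p_cfos = 1 gives fraction exactly 1
  tab1 <- gen_cell_table(sim_config(seed = 19, p_cfos = 1), n_animals = 1L)
  expect_equal(marker_fractions(tab1, "mPOA",
                                per_animal = FALSE)$frac_cfos_in_gal, 1)
})

test_that("lognormalize applies ln(1 + scale * count / total)", {
  m <- matrix(c(0L, 1L, 3L,
                0L, 9999L, 1L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  ln <- lognormalize(m, scale = 1e4)
  expect_equal(ln["g1", "c1"], 0)
  expect_equal(ln["g2", "c1"], log(1 + 1e4 * 1 / 4))
  # cell with total equal to scale and count 1 gives ln(2)
  expect_equal(lognormalize(matrix(c(1L, rep(1L, 9999)), ncol = 1),
                            scale = 1e4)[1, 1], log(2))
  # doubling a cell's counts leaves normalized values unchanged
  expect_equal(lognormalize(m * 2L), lognormalize(m))
  m0 <- cbind(m, c0 = c(0L, 0L, 0L))
  expect_warning(ln0 <- lognormalize(m0), "all-zero")
  expect_equal(ncol(ln0), 2)
})

test_that("dotplot summary equals brute-force counting and is order
           invariant", {
  cfg <- sim_config(seed = 20, n_cells_per_group = 60L)
  sce <- gen_expression(cfg)
  dp <- dotplot_summary(sce)
  counts <- SummarizedExperiment::assay(sce, "counts")
  cd <- SummarizedExperiment::colData(sce)
  for (i in sample(nrow(dp), 10)) {
    sel <- cd$cluster == dp$cluster[i] & cd$sex == dp$sex[i]
    expect_equal(dp$fraction_expressing[i],
                 mean(counts[dp$gene[i], sel] > 0))
  }
  # z-scaling across each gene's groups
  for (g in unique(dp$gene)[1:3]) {
    sub <- dp[dp$gene == g, ]
    if (stats::sd(sub$mean_expression) > 0) {
      expect_equal(mean(sub$scaled_mean), 0, tolerance = 1e-12)
      expect_equal(stats::sd(sub$scaled_mean), 1, tolerance = 1e-12)
    }
  }
  # permuting cells and genes leaves the summary unchanged
  perm <- sample(ncol(sce))
  dp2 <- dotplot_summary(sce[rev(rownames(sce)), perm])
  key <- function(d) {
    d <- d[order(d$gene, d$cluster, d$sex), ]
    rownames(d) <- NULL
    attr(d, "missing_genes") <- NULL
    d
  }
  expect_equal(key(dp2), key(dp))
  # missing genes are reported, not dropped silently
  expect_warning(dpm <- dotplot_summary(sce, genes = c("Tlr3", "Nope")),
                 "Nope")
  expect_equal(attr(dpm, "missing_genes"), "Nope")
})

test_that("configured expressing fractions are recovered within 3 SE", {
  ef <- expand.grid(gene = c("Tlr3", "Il6r"), cluster = c("i8", "i16"),
                    sex = c(0L, 1L), stringsAsFactors = FALSE)
  ef$fraction <- c(0.6, 0.3, 0.2, 0.8, 0.5, 0.1, 0.9, 0.4)
  cfg <- sim_config(seed = 22, expr_fractions = ef,
                    n_cells_per_group = 2000L)
  dp <- dotplot_summary(gen_expression(cfg), genes = c("Tlr3", "Il6r"))
  merged <- merge(dp, ef, by = c("gene", "cluster", "sex"))
  se <- sqrt(merged$fraction * (1 - merged$fraction) / 2000)
  expect_true(all(abs(merged$fraction_expressing - merged$fraction) <=
                    3 * pmax(se, 1e-3)))
})
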