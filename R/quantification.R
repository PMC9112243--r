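#' Generate a synthetic marker-count cell table with ground truth
#'
#' Emulates confocal counting of galanin (Gal) and phospho-c-Fos labels
#' over DAPI-stained cells: every cell is DAPI-positive, a cell is Gal+
#' with probability `p_gal`, and a Gal+ cell is c-Fos+ with probability
#' `p_cfos` (c-Fos is evaluated only in Gal+ cells).  Cells are spread
#' over animals x two sections x two hemispheres in both ROIs (mPOA and
#' vBNST), mirroring the acquisition hierarchy.
#'
#' @param cfg [sim_config()].
#' @param n_animals animals per table.
#' @param rois ROI labels.
#' @return data.frame (`cell_id`, `roi`, `animal`, `section`, `hemisphere`,
#'   `dapi`, `gal`, `cfos`) with a `truth` attribute carrying `p_gal`,
#'   `p_cfos`.
#' @export
gen_cell_table <- function(cfg, n_animals = 5L, rois = c("mPOA", "vBNST")) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, "cells"))
  per_image <- max(1L, cfg$n_cells %/% 4L)
  rows <- list()
  cid <- 0L
  for (roi in rois) for (a in seq_len(n_animals))
    for (s in 1:2) for (h in c("L", "R")) {
      n <- per_image
      gal <- stats::runif(n) < cfg$p_gal
      cfos <- gal & (stats::runif(n) < cfg$p_cfos)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = sprintf("%s_a%d_s%d_%s_%04d", roi, a, s, h,
                          cid + seq_len(n)),
        roi = roi, animal = sprintf("a%d", a), section = s,
        hemisphere = h, dapi = TRUE, gal = gal, cfos = cfos,
        stringsAsFactors = FALSE)
      cid <- cid + n
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(p_gal = cfg$p_gal, p_cfos = cfg$p_cfos)
  out
}

#' Marker fractions for one ROI
#'
#' `frac_cfos_in_gal` is the fraction of Gal+ cells that are also c-Fos+;
#' `frac_gal_per_dapi` is the Gal+ count normalized to DAPI.  With
#' `per_animal = TRUE` (default) fractions are computed per image
#' (section x hemisphere), averaged to the animal, and the per-animal
#' values returned alongside their mean, matching the
#' section -> hemisphere -> animal -> group aggregation hierarchy.
#'
#' @param table cell table as from [gen_cell_table()].
#' @param roi ROI to quantify.
#' @param per_animal aggregate per animal before averaging.
#' @return list with `frac_cfos_in_gal`, `frac_gal_per_dapi`, per-animal
#'   data.frame `by_animal`, and `no_gal` flag (TRUE when the ROI has no
#'   Gal+ cell; the first fraction is then `NA`).
#' @export
marker_fractions <- function(table, roi, per_animal = TRUE) {
  stopifnot(all(c("roi", "dapi", "gal", "cfos") %in% names(table)))
  tb <- table[table$roi == roi, , drop = FALSE]
  if (!nrow(tb)) stop("roi '", roi, "' not present in table")
  frac <- function(x) {
    n_gal <- sum(x$gal); n_dapi <- sum(x$dapi)
    c(cfos_in_gal = if (n_gal > 0) sum(x$cfos & x$gal) / n_gal else NA_real_,
      gal_per_dapi = if (n_dapi > 0) n_gal / n_dapi else NA_real_)
  }
  if (!per_animal || is.null(tb$animal)) {
    f <- frac(tb)
    return(list(frac_cfos_in_gal = unname(f["cfos_in_gal"]),
                frac_gal_per_dapi = unname(f["gal_per_dapi"]),
                by_animal = NULL,
                no_gal = sum(tb$gal) == 0L))
  }
  img_key <- interaction(tb$animal,
                         if (!is.null(tb$section)) tb$section else 1,
                         if (!is.null(tb$hemisphere)) tb$hemisphere else 1,
                         drop = TRUE)
  per_img <- t(vapply(split(tb, img_key), frac, numeric(2)))
  animal_of <- vapply(split(tb$animal, img_key), `[`, character(1), 1)
  by_animal <- data.frame(
    animal = unique(animal_of),
    frac_cfos_in_gal = vapply(unique(animal_of), function(a)
      mean(per_img[animal_of == a, "cfos_in_gal"], na.rm = TRUE),
      numeric(1)),
    frac_gal_per_dapi = vapply(unique(animal_of), function(a)
      mean(per_img[animal_of == a, "gal_per_dapi"], na.rm = TRUE),
      numeric(1)),
    stringsAsFactors = FALSE)
  list(frac_cfos_in_gal = mean(by_animal$frac_cfos_in_gal, na.rm = TRUE),
       frac_gal_per_dapi = mean(by_animal$frac_gal_per_dapi, na.rm = TRUE),
       by_animal = by_animal,
       no_gal = sum(tb$gal) == 0L)
}

#' Default gene panel for the immune-signalling expression analysis
#'
#' Receptors and transducers of viral-mimic (Poly I:C) signalling assessed
#' across galanin-positive hypothalamic clusters.
#'
#' @return character vector of gene symbols.
#' @export
default_gene_panel <- function() {
  c("Il6r", "Il1r1", "Jak1", "Jak2",
    paste0("Stat", 1:6),
    "Ifnar1", "Ifnar2", "Ifngr1", "Ifngr2",
    "Tlr3", "Tlr4", "Myd88", "Ticam1", "Tirap",
    "Traf3", "Traf6", "Ikbkb", "Chuk",
    "Nfkb1", "Nfkb2", "Mapk14")
}

#' Generate a synthetic cells x genes count matrix with ground truth
#'
#' Draws, for each (gene, cluster, sex) group, cells expressing the gene
#' with the configured probability; expressing cells receive
#' `1 + NegBin(nb_mean, nb_dispersion)` counts so the expressing fraction
#' is exactly the configured probability.  Clusters default to the three
#' galanin-positive hypothalamic clusters (`i8`, `i16`, `i18`); sexes are
#' coded 0 (female) and 1 (male) and generated for both.
#'
#' @param cfg [sim_config()]; `cfg$expr_fractions` may supply a
#'   (gene, cluster, sex, fraction) table, otherwise a deterministic
#'   default pattern over the panel is used.
#' @return [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay, `colData` columns `cluster` and `sex`, and the true fraction
#'   table in `metadata(sce)$expr_fractions`.
#' @export
gen_expression <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, "expression"))
  clusters <- c("i8", "i16", "i18")
  sexes <- c(0L, 1L)
  genes <- default_gene_panel()
  grid <- expand.grid(gene = genes, cluster = clusters, sex = sexes,
                      stringsAsFactors = FALSE)
  # deterministic, varied default pattern
  gi <- match(grid$gene, genes)
  ci <- match(grid$cluster, clusters)
  grid$fraction <- round(0.05 + 0.85 *
                           (((gi * 3 + ci * 7 + grid$sex * 11) %% 13) / 12),
                         3)
  if (!is.null(cfg$expr_fractions)) {
    # user rows override the default pattern group-wise
    usr <- cfg$expr_fractions
    key <- function(d) paste(d$gene, d$cluster, d$sex)
    hit <- match(key(grid), key(usr))
    grid$fraction[!is.na(hit)] <- usr$fraction[hit[!is.na(hit)]]
    extra <- usr[!(key(usr) %in% key(grid)), , drop = FALSE]
    if (nrow(extra)) grid <- rbind(grid, extra[names(grid)])
  }
  ef <- grid
  genes <- unique(c(genes, ef$gene))
  groups <- unique(ef[c("cluster", "sex")])
  mats <- list()
  meta <- list()
  for (g in seq_len(nrow(groups))) {
    cl <- groups$cluster[g]; sx <- groups$sex[g]
    n <- cfg$n_cells_per_group
    sub <- ef[ef$cluster == cl & ef$sex == sx, , drop = FALSE]
    m <- matrix(0L, nrow = length(genes), ncol = n,
                dimnames = list(genes, NULL))
    for (i in seq_len(nrow(sub))) {
      gene <- sub$gene[i]
      expr <- stats::runif(n) < sub$fraction[i]
      k <- sum(expr)
      if (k > 0)
        m[gene, expr] <- 1L + as.integer(
          stats::rnbinom(k, mu = cfg$nb_mean, size = cfg$nb_dispersion))
    }
    mats[[g]] <- m
    meta[[g]] <- data.frame(cluster = rep(cl, n), sex = rep(sx, n))
  }
  counts <- do.call(cbind, mats)
  colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  cd <- do.call(rbind, meta)
  rownames(cd) <- colnames(counts)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cd))
  S4Vectors::metadata(sce)$expr_fractions <- ef
  sce
}

#' Library-size log-normalization
#'
#' `value = ln(1 + scale * count / cell_total)`, the standard per-cell
#' normalization for droplet single-cell counts.  Cells with zero total
#' counts are dropped with a warning.
#'
#' @param counts genes x cells integer matrix, or a SingleCellExperiment
#'   with a `counts` assay.
#' @param scale library-size scale factor, default 10000.
#' @return matrix of normalized values (genes x cells); for a
#'   SingleCellExperiment input, the object with a `lognorm` assay added.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  if (methods::is(counts, "SingleCellExperiment")) {
    m <- SummarizedExperiment::assay(counts, "counts")
    tot <- colSums(m)
    if (any(tot == 0)) {
      warning(sum(tot == 0), " all-zero cells dropped")
      counts <- counts[, tot > 0]
      m <- SummarizedExperiment::assay(counts, "counts")
      tot <- tot[tot > 0]
    }
    SummarizedExperiment::assay(counts, "lognorm") <-
      log1p(sweep(m, 2, tot, "/") * scale)
    return(counts)
  }
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " all-zero cells dropped")
    counts <- counts[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  log1p(sweep(counts, 2, tot, "/") * scale)
}

#' Dot-plot summary per (gene, cluster, sex)
#'
#' For each requested gene and each cluster x sex group: the fraction of
#' cells with count above `min_count` (default 0, the dot-plot convention
#' for "expressing"), the mean log-normalized expression, and a z-scaled
#' mean across the groups of each gene (for display).  Requested genes
#' missing from the matrix are reported in the `missing_genes` attribute,
#' not silently dropped.
#'
#' @param sce SingleCellExperiment with `counts` assay and colData columns
#'   `cluster` and `sex`, as from [gen_expression()].
#' @param genes genes to summarize; default all rows.
#' @param min_count expression threshold; a cell expresses a gene when
#'   `count > min_count`.
#' @param scale passed to [lognormalize()].
#' @return data.frame (`gene`, `cluster`, `sex`, `fraction_expressing`,
#'   `mean_expression`, `scaled_mean`) with attribute `missing_genes`.
#' @export
dotplot_summary <- function(sce, genes = NULL, min_count = 0, scale = 1e4) {
  stopifnot(methods::is(sce, "SingleCellExperiment"))
  cd <- SummarizedExperiment::colData(sce)
  stopifnot(all(c("cluster", "sex") %in% names(cd)))
  if (is.null(genes)) genes <- rownames(sce)
  missing <- setdiff(genes, rownames(sce))
  genes <- intersect(genes, rownames(sce))
  sce <- lognormalize(sce, scale = scale)
  counts <- SummarizedExperiment::assay(sce, "counts")
  ln <- SummarizedExperiment::assay(sce, "lognorm")
  cd <- SummarizedExperiment::colData(sce)
  key <- interaction(cd$cluster, cd$sex, drop = TRUE)
  groups <- levels(key)
  out <- list()
  for (g in genes) {
    fr <- vapply(groups, function(k)
      mean(counts[g, key == k] > min_count), numeric(1))
    mu <- vapply(groups, function(k)
      mean(ln[g, key == k]), numeric(1))
    sdv <- stats::sd(mu)
    scaled <- if (is.na(sdv) || sdv == 0) rep(0, length(mu))
              else (mu - mean(mu)) / sdv
    parts <- strsplit(groups, ".", fixed = TRUE)
    out[[g]] <- data.frame(
      gene = g,
      cluster = vapply(parts, `[`, character(1), 1),
      sex = as.integer(vapply(parts, `[`, character(1), 2)),
      fraction_expressing = unname(fr),
      mean_expression = unname(mu),
      scaled_mean = unname(scaled),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(missing))
    warning("genes not in matrix: ", paste(missing, collapse = ", "))
  attr(res, "missing_genes") <- missing
  res
}
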