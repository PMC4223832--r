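#' Fraction of shared spacers restricted to one location and/or biome
#'
#' Among canonical spacers observed in two or more strains, the percentage
#' restricted to a single location OR a single biome (the two component
#' restrictions are also reported separately). Merging locations can only
#' keep or increase each spacer's restriction status count, never split it,
#' so the fraction is monotone non-decreasing under location merges of the
#' restricted set and non-increasing as locations are subdivided.
#'
#' @param catalog a `spacer_catalog`.
#' @param metadata strain metadata with non-empty `location` and `biome`.
#' @return list with `fraction` (percent), `fraction_location`,
#'   `fraction_biome`, `n_shared`, and `table` (per shared spacer: strains,
#'   locations, biomes, restriction flags).
#' @export
location_restricted_fraction <- function(catalog, metadata) {
  stopifnot(all(c("location", "biome") %in% names(metadata)))
  if (any(!nzchar(metadata$location)) || any(!nzchar(metadata$biome))) {
    stop("location and biome must be non-empty for all strains")
  }
  shared <- catalog$table[catalog$table$shared, , drop = FALSE]
  if (nrow(shared) == 0L) {
    return(list(fraction = NA_real_, fraction_location = NA_real_,
                fraction_biome = NA_real_, n_shared = 0L,
                table = data.frame(canonical = character(0), strains = character(0),
                                   locations = character(0), biomes = character(0),
                                   restricted_to_location = logical(0),
                                   restricted_to_biome = logical(0),
                                   restricted = logical(0), stringsAsFactors = FALSE)))
  }
  rows <- lapply(seq_len(nrow(shared)), function(i) {
    strains <- strsplit(shared$strains[i], ",", fixed = TRUE)[[1L]]
    idx <- match(strains, metadata$strain_id)
    locs <- sort(unique(metadata$location[idx]))
    biomes <- sort(unique(metadata$biome[idx]))
    data.frame(canonical = shared$canonical[i],
               strains = shared$strains[i],
               locations = paste(locs, collapse = ","),
               biomes = paste(biomes, collapse = ","),
               restricted_to_location = length(locs) == 1L,
               restricted_to_biome = length(biomes) == 1L,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$restricted <- tab$restricted_to_location | tab$restricted_to_biome
  list(fraction = round(100 * mean(tab$restricted), 1),
       fraction_location = round(100 * mean(tab$restricted_to_location), 1),
       fraction_biome = round(100 * mean(tab$restricted_to_biome), 1),
       n_shared = nrow(tab),
       table = tab)
}

#' Normalize per-strain counts
#'
#' Counts per megabase of genome (`per = "mb"`) or per annotated gene
#' (`per = "gene"`).
#'
#' @param counts numeric vector of per-strain counts.
#' @param denom genome sizes in bp (`per = "mb"`) or gene counts.
#' @param per `"mb"` or `"gene"`.
#' @return numeric vector of normalized values.
#' @export
normalize_counts <- function(counts, denom, per = c("mb", "gene")) {
  per <- match.arg(per)
  stopifnot(length(counts) == length(denom), all(denom > 0))
  if (per == "mb") counts / (denom / 1e6) else counts / denom
}

stat_result <- function(test, statistic, p_value, group_sizes,
                        normalization = "none", extra = NULL) {
  structure(c(list(test = test, statistic = unname(statistic),
                   p_value = unname(p_value), group_sizes = group_sizes,
                   normalization = normalization), extra),
            class = "stat_result")
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based one-way analysis of variance across two or more groups, with
#' the ties-corrected H statistic and a chi-square reference distribution on
#' k - 1 degrees of freedom (via [stats::kruskal.test()]). The pipeline uses
#' it as the omnibus gate before pairwise rank-sum tests.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @param normalization label recorded in the result (`"none"`, `"per_mb"`,
#'   `"per_gene"`).
#' @return a `stat_result` with `test`, `statistic` (H), `p_value`,
#'   `group_sizes`, `normalization`.
#' @export
kruskal_wallis <- function(groups, normalization = "none") {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L))
  kt <- stats::kruskal.test(groups)
  H <- unname(kt$statistic)
  p <- kt$p.value
  if (is.nan(H)) { H <- 0; p <- 1 }  # all observations tied: no rank variance
  stat_result("kruskal_wallis", H, p, lengths(groups), normalization)
}

#' Wilcoxon rank-sum test for one sample pair
#'
#' Two-sided rank-sum test, reported with the rank sum W of the first
#' sample. The exact null distribution is enumerated when the combined
#' sample size is at most 10 and there are no ties; otherwise the normal
#' approximation with continuity correction is used (via
#' [stats::wilcox.test()]). In pipeline mode this runs only after a
#' significant omnibus result.
#'
#' @param a,b numeric samples (non-empty).
#' @param normalization label recorded in the result.
#' @return a `stat_result`; `statistic` is the rank sum of `a`.
#' @export
wilcoxon_ranksum <- function(a, b, normalization = "none") {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  W <- sum(ranks[seq_along(a)])
  ties <- any(duplicated(c(a, b)))
  exact <- n <= 10L && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- min(1, wt$p.value)
  stat_result("wilcoxon_ranksum", W, p, c(length(a), length(b)), normalization,
              extra = list(exact = exact))
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Two-sided pooled-variance t-test with n_a + n_b - 2 degrees of freedom
#' (via [stats::t.test()] with `var.equal = TRUE`). Used to compare the
#' fraction of prophage-matching spacers between prophage-harbouring and
#' prophage-free strains.
#'
#' @param a,b numeric samples with at least 2 values each.
#' @param normalization label recorded in the result.
#' @return a `stat_result` with the t statistic.
#' @export
two_sample_t <- function(a, b, normalization = "none") {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(c(a - mean(a), b - mean(b))) == 0) stop("zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  stat_result("two_sample_t", tt$statistic, tt$p.value,
              c(length(a), length(b)), normalization,
              extra = list(df = unname(tt$parameter)))
}

#' Least-squares regression with R-squared
#'
#' Ordinary least squares of y on x; R-squared equals the squared Pearson
#' correlation. Used to test whether CRISPR/spacer/cas content correlates
#' with prophage content.
#'
#' @param x,y numeric vectors (>= 3 points, var(x) > 0).
#' @param normalization label recorded in the result.
#' @return a `stat_result` with the slope as `statistic` plus `intercept`
#'   and `r_squared`.
#' @export
least_squares_r2 <- function(x, y, normalization = "none") {
  stopifnot(length(x) == length(y), length(x) >= 3L, stats::var(x) > 0)
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # warns on exact fits
  # a constant response has no explainable variance: R^2 = 0 by definition
  r2 <- if (stats::var(y) == 0) 0 else unname(stats::cor(x, y)^2)
  p <- if (stats::var(y) == 0) 1 else s$coefficients[2L, 4L]
  stat_result("least_squares", stats::coef(fit)[2L], p, length(x), normalization,
              extra = list(intercept = unname(stats::coef(fit)[1L]),
                           r_squared = r2))
}

#' The full statistical battery over per-strain summaries
#'
#' Applies the omnibus-then-pairwise scheme: per-Mb locus counts compared by
#' species, location, biome and (within species) phylotype with the
#' Kruskal-Wallis test; pairwise rank-sum tests only where the omnibus p is
#' below `alpha`; the t-test comparing prophage-matching spacer fractions
#' between strains with and without prophages; and least-squares R-squared
#' of locus/spacer counts against prophage counts. No multiple-testing
#' correction is applied.
#'
#' @param per_strain per-strain table ([per_strain_summary()]).
#' @param metadata strain metadata.
#' @param prophages prophage region table with `strain_id` (optional).
#' @param match_by_strain optional [match_summary()] rows (`grouping ==
#'   "strain"`) for the prophage t-test.
#' @param alpha omnibus significance gate.
#' @return data.frame of test results (test, comparison, statistic, p_value,
#'   groups).
#' @export
run_stat_battery <- function(per_strain, metadata, prophages = NULL,
                             match_by_strain = NULL, alpha = 0.05) {
  df <- merge(per_strain, metadata, by = "strain_id")
  out <- list()
  add <- function(res, comparison) {
    out[[length(out) + 1L]] <<- data.frame(
      test = res$test, comparison = comparison,
      statistic = round(unname(res$statistic), 4),
      p_value = signif(res$p_value, 4),
      groups = paste(res$group_sizes, collapse = ","),
      stringsAsFactors = FALSE)
  }
  omnibus_then_pairwise <- function(values, labels, comparison) {
    keep <- !is.na(labels) & nzchar(labels)
    values <- values[keep]; labels <- labels[keep]
    gr <- split(values, labels)
    gr <- gr[lengths(gr) >= 1L]
    if (length(gr) < 2L) return(invisible(NULL))
    kw <- kruskal_wallis(gr, normalization = "per_mb")
    add(kw, comparison)
    if (!is.na(kw$p_value) && kw$p_value < alpha) {
      nm <- names(gr)
      for (i in 1:(length(nm) - 1L)) for (j in (i + 1L):length(nm)) {
        if (length(gr[[i]]) >= 1L && length(gr[[j]]) >= 1L) {
          wr <- wilcoxon_ranksum(gr[[i]], gr[[j]], normalization = "per_mb")
          add(wr, paste0(comparison, ":", nm[i], "_vs_", nm[j]))
        }
      }
    }
  }
  loci_mb <- normalize_counts(df$n_loci, df$genome_size, "mb")
  if ("species" %in% names(df)) omnibus_then_pairwise(loci_mb, df$species, "loci_per_mb~species")
  if ("location" %in% names(df)) omnibus_then_pairwise(loci_mb, df$location, "loci_per_mb~location")
  if ("biome" %in% names(df)) omnibus_then_pairwise(loci_mb, df$biome, "loci_per_mb~biome")
  if (all(c("species", "phylotype") %in% names(df))) {
    for (sp in unique(df$species)) {
      sub <- df[df$species == sp, , drop = FALSE]
      if (length(unique(sub$phylotype)) >= 2L) {
        omnibus_then_pairwise(normalize_counts(sub$n_loci, sub$genome_size, "mb"),
                              sub$phylotype, paste0("loci_per_mb~phylotype[", sp, "]"))
      }
    }
  }
  if (!is.null(prophages)) {
    pro_counts <- vapply(df$strain_id, function(s) sum(prophages$strain_id == s, na.rm = TRUE), 0L)
    if (!is.null(match_by_strain)) {
      frac <- match_by_strain$pct_prophage[match(df$strain_id, match_by_strain$group)]
      with_p <- frac[pro_counts > 0L]; without_p <- frac[pro_counts == 0L]
      if (length(with_p) >= 2L && length(without_p) >= 2L &&
          stats::var(c(with_p - mean(with_p), without_p - mean(without_p))) > 0) {
        add(two_sample_t(without_p, with_p), "pct_prophage_match~prophage_free_vs_harbouring")
      }
    }
    for (var in c("n_loci", "n_spacers")) {
      if (stats::var(pro_counts) > 0 && length(pro_counts) >= 3L) {
        r <- least_squares_r2(pro_counts, df[[var]])
        out[[length(out) + 1L]] <- data.frame(
          test = "least_squares", comparison = paste0(var, "~prophages"),
          statistic = round(r$r_squared, 4), p_value = signif(r$p_value, 4),
          groups = as.character(length(pro_counts)), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(test = character(0), comparison = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      groups = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
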