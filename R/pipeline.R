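#' Study configuration
#'
#' Bundles everything [run_study()] needs: the leaf source (synthetic
#' progeny specifications or a contour file), the bootstrap settings, the
#' reference values for the hypothesis battery, and the clustering
#' controls. The default references are the published anchor points for
#' the Montgomery constant in coffee — the lowest (0.64340) and highest
#' (0.70125) values reported for the species, the classical ovate-leaf
#' correction factor 2/3 — and the similarity exponent 2 for the power
#' law.
#'
#' @param progenies list of [progeny_spec()] objects (synthetic input).
#' @param input path to a contour CSV/JSON (measured input); exactly one
#'   of `progenies` / `input` must be given.
#' @param bootstrap a [bootstrap_config()].
#' @param references named list with elements `h2`, `h3`, `h4` (Montgomery
#'   constant references) and `h5` (similarity exponent reference).
#' @param k_range candidate cluster counts for [select_k()].
#' @param n_stations width-grid resolution (see [leaf_width()]).
#' @param stability_B bootstrap resamples for [cluster_stability()].
#' @param gap_B reference datasets for the gap index in [select_k()].
#' @param output_dir if non-`NULL`, [run_study()] writes the report there.
#' @return object of class `study_config`.
#' @export
study_config <- function(progenies = NULL, input = NULL,
                         bootstrap = bootstrap_config(),
                         references = list(h2 = 0.64340, h3 = 0.70125,
                                           h4 = 2 / 3, h5 = 2),
                         k_range = 2:6, n_stations = 2001L,
                         stability_B = 100L, gap_B = 50L,
                         output_dir = NULL) {
  if (is.null(progenies) == is.null(input))
    stop("provide exactly one of `progenies` or `input`", call. = FALSE)
  if (!is.null(progenies)) {
    if (!is.list(progenies) ||
        !all(vapply(progenies, inherits, TRUE, "progeny_spec")))
      stop("`progenies` must be a list of progeny_spec objects",
           call. = FALSE)
  }
  if (!inherits(bootstrap, "bootstrap_config"))
    stop("`bootstrap` must be a bootstrap_config", call. = FALSE)
  need <- c("h2", "h3", "h4", "h5")
  if (!all(need %in% names(references)) ||
      !all(vapply(references[need], function(r) is.numeric(r) && r > 0, TRUE)))
    stop("`references` must contain positive h2, h3, h4, h5", call. = FALSE)
  structure(list(progenies = progenies, input = input, bootstrap = bootstrap,
                 references = references, k_range = as.integer(k_range),
                 n_stations = as.integer(n_stations),
                 stability_B = as.integer(stability_B),
                 gap_B = as.integer(gap_B), output_dir = output_dir),
            class = "study_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full leaf-size study
#'
#' End-to-end pipeline: obtain leaf contours (simulate the configured
#' progenies or read the input file), measure every leaf, fit the
#' Montgomery and power-law models with percentile-bootstrap confidence
#' intervals for every progeny, each hybridization consolidation and the
#' pooled data, evaluate the five-hypothesis battery, and analyse progeny
#' shape (ellipticity, multivariate tests, PAM clustering, correlations,
#' PCA). Deterministic under a fixed bootstrap seed.
#'
#' @param config a [study_config()].
#' @return object of class `study_report`: list with `table1` (Montgomery
#'   fits + H1-H4), `table2` (power-law fits + H5), `measurements`,
#'   `shape_records`, `clusters`, `tests`, `provenance`. If
#'   `config$output_dir` is set the report is also written there (see
#'   [write_report()]).
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config"))
    stop("`config` must be a study_config", call. = FALSE)

  contours <- stage("input", {
    if (!is.null(config$input)) read_contours(config$input)
    else unlist(lapply(config$progenies, sample_progeny), recursive = FALSE)
  })
  meas <- stage("measure", measure_leaves(contours, config$n_stations))

  cfg <- config$bootstrap
  refs <- config$references
  prog_ids <- unique(meas$progeny_id)
  hyb_types <- intersect(c("IntraH", "InterH"), unique(meas$hybridization))
  groups <- c(stats::setNames(lapply(prog_ids, function(p)
                meas[meas$progeny_id == p, , drop = FALSE]), prog_ids),
              stats::setNames(lapply(hyb_types, function(h)
                meas[meas$hybridization == h, , drop = FALSE]), hyb_types),
              list(Pd = meas))
  types <- c(meas$hybridization[match(prog_ids, meas$progeny_id)],
             hyb_types, "Pd")

  fits <- stage("fit", lapply(names(groups), function(g) {
    d <- groups[[g]]
    m1 <- fit_montgomery(d)
    m2 <- fit_power_law(d)
    ci1 <- bootstrap_ci(d, "M1_alpha", cfg, stream = g)
    ci2a <- bootstrap_ci(d, "M2_alpha", cfg, stream = g)
    ci2b <- bootstrap_ci(d, "M2_beta", cfg, stream = g)
    m1$ci <- c(ci1$low, ci1$high)
    m2$alpha_ci <- c(ci2a$low, ci2a$high)
    m2$beta_ci <- c(ci2b$low, ci2b$high)
    h1 <- if (g != "Pd") test_vs_pooled(d, meas, cfg, stream = g) else NULL
    list(group = g, m1 = m1, m2 = m2,
         h1 = h1,
         h2 = test_reference(m1$ci, refs$h2, "H2"),
         h3 = test_reference(m1$ci, refs$h3, "H3"),
         h4 = test_reference(m1$ci, refs$h4, "H4"),
         h5 = test_reference(m2$beta_ci, refs$h5, "H5"))
  }))

  table1 <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(group = f$group, type = types[i], alpha = f$m1$alpha,
               ci_low = f$m1$ci[1L], ci_high = f$m1$ci[2L],
               h1_supported = if (is.null(f$h1)) NA else f$h1$supported,
               h1_direction = if (is.null(f$h1)) NA_character_
                              else f$h1$direction,
               h1_p = if (is.null(f$h1)) NA_real_ else f$h1$p_value,
               h2_supported = f$h2$supported, h2_direction = f$h2$direction,
               h3_supported = f$h3$supported, h3_direction = f$h3$direction,
               h4_supported = f$h4$supported, h4_direction = f$h4$direction,
               rmse = f$m1$rmse, n = f$m1$n, stringsAsFactors = FALSE)
  }))
  table2 <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(group = f$group, type = types[i], alpha = f$m2$alpha,
               alpha_ci_low = f$m2$alpha_ci[1L],
               alpha_ci_high = f$m2$alpha_ci[2L],
               beta = f$m2$beta, beta_ci_low = f$m2$beta_ci[1L],
               beta_ci_high = f$m2$beta_ci[2L],
               h5_supported = f$h5$supported, h5_direction = f$h5$direction,
               rmse = f$m2$rmse, n = f$m2$n, converged = f$m2$converged,
               stringsAsFactors = FALSE)
  }))

  shape <- stage("shape", {
    rec <- do.call(rbind, lapply(prog_ids, function(p) {
      d <- meas[meas$progeny_id == p, , drop = FALSE]
      al <- table1$alpha[table1$group == p]
      data.frame(progeny_id = p, hybridization = d$hybridization[1L],
                 mean_LS = mean(d$LS_cm2), mean_RWL = mean(d$RWL),
                 EI = ellipticity_index(al), stringsAsFactors = FALSE)
    }))
    feats <- as.matrix(rec[, c("mean_LS", "mean_RWL", "EI")])
    rownames(feats) <- rec$progeny_id
    tests <- list()
    clusters <- NULL
    if (length(hyb_types) == 2L) {
      A <- feats[rec$hybridization == "IntraH", , drop = FALSE]
      B <- feats[rec$hybridization == "InterH", , drop = FALSE]
      tests$hotelling_hybridization <- tryCatch(hotelling_t2(A, B),
                                                error = function(e)
                                                  conditionMessage(e))
    }
    tests$mardia <- tryCatch(mardia_test(feats),
                             error = function(e) conditionMessage(e))
    if (length(hyb_types) == 2L)
      tests$box_m <- tryCatch(
        box_m(split.data.frame(feats, rec$hybridization)),
        error = function(e) conditionMessage(e))
    tests$spearman <- tryCatch(spearman_bonferroni(feats),
                               error = function(e) conditionMessage(e))

    n_prog <- nrow(rec)
    if (n_prog >= 4L) {
      kr <- config$k_range[config$k_range <= n_prog - 1L &
                           config$k_range >= 2L]
      if (!length(kr)) kr <- 2L
      k <- select_k(feats, kr, gap_B = config$gap_B, seed = cfg$seed)
      clusters <- pam_cluster(feats, k)
      clusters$stability <- cluster_stability(feats, k,
                                              B = config$stability_B,
                                              seed = cfg$seed)
      rec$cluster <- clusters$labels
      if (k >= 2L) {
        g1 <- feats[clusters$labels == 1L, , drop = FALSE]
        g2 <- feats[clusters$labels != 1L, , drop = FALSE]
        tests$hotelling_clusters <- tryCatch(hotelling_t2(g1, g2),
                                             error = function(e)
                                               conditionMessage(e))
      }
      if (k == 2L && length(hyb_types) == 2L) {
        tab <- table(factor(rec$cluster), factor(rec$hybridization))
        tests$chi2_cluster_hybridization <- tryCatch(
          chi2_homogeneity(unclass(tab)),
          error = function(e) conditionMessage(e))
      }
      tests$pca <- pca_project(feats, 2L)
    }
    list(records = rec, clusters = clusters, tests = tests)
  })

  cfg_json <- jsonlite::toJSON(serialize_config(config), auto_unbox = TRUE,
                               digits = NA)
  report <- structure(
    list(table1 = table1, table2 = table2, measurements = meas,
         shape_records = shape$records, clusters = shape$clusters,
         tests = shape$tests,
         provenance = list(config = serialize_config(config),
                           config_hash = fnv1a(cfg_json),
                           seed = cfg$seed,
                           n_leaves = nrow(meas),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "study_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d leaves, %d fitted groups\n",
              nrow(x$measurements), nrow(x$table1)))
  cat("Montgomery constants by group:\n")
  print(x$table1[, c("group", "type", "alpha", "ci_low", "ci_high",
                     "rmse", "n")], row.names = FALSE, digits = 5)
  if (!is.null(x$clusters))
    cat(sprintf("PAM clustering of %d progenies: k = %d, silhouette = %.3f\n",
                nrow(x$shape_records), x$clusters$k, x$clusters$silhouette))
  invisible(x)
}

serialize_config <- function(config) {
  list(progenies = lapply(config$progenies, function(p)
         list(progeny_id = p$progeny_id, hybridization = p$hybridization,
              n_leaves = p$n_leaves, family = p$shape$family,
              a = p$shape$a, b = p$shape$b, rwl = p$shape$rwl,
              length_range = p$length_range, noise_sd = p$noise_sd,
              rwl_sd = p$rwl_sd, n_vertices = p$n_vertices, seed = p$seed)),
       input = config$input,
       bootstrap = unclass(config$bootstrap),
       references = config$references, k_range = config$k_range,
       n_stations = config$n_stations, stability_B = config$stability_B,
       gap_B = config$gap_B)
}

# FNV-1a string hash, reported as hex; cheap provenance fingerprint
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Write a study report to a directory
#'
#' Emits `table1.csv` (Montgomery fits and hypotheses H1-H4),
#' `table2.csv` (power-law fits and H5), `measurements.csv`,
#' `shape_records.csv` (per-progeny means, ellipticity and cluster),
#' `tests.json` (multivariate test battery, stability, PCA) and
#' `metadata.json` (provenance). On any failure partially written files
#' are removed.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "study_report"))
    stop("`report` must be a study_report", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    stop(sprintf("[stage report] %s", conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    emit <- function(df, name, num_cols) {
      p <- file.path(dir, name)
      utils::write.csv(format_numeric(df, num_cols), p, row.names = FALSE,
                       quote = FALSE)
      written <<- c(written, p)
    }
    emit(report$table1, "table1.csv",
         c("alpha", "ci_low", "ci_high", "h1_p", "rmse"))
    emit(report$table2, "table2.csv",
         c("alpha", "alpha_ci_low", "alpha_ci_high", "beta", "beta_ci_low",
           "beta_ci_high", "rmse"))
    emit(report$measurements, "measurements.csv",
         c("L_cm", "W_cm", "LS_cm2", "RWL"))
    emit(report$shape_records, "shape_records.csv",
         c("mean_LS", "mean_RWL", "EI"))
    tp <- file.path(dir, "tests.json")
    jsonlite::write_json(simplify_tests(report), tp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    written <- c(written, tp)
    mp <- file.path(dir, "metadata.json")
    jsonlite::write_json(report$provenance, mp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, mp)
  }, error = on_fail)
  invisible(dir)
}

simplify_tests <- function(report) {
  out <- report$tests
  if (!is.null(report$clusters)) {
    cl <- report$clusters
    out$clustering <- list(k = cl$k, medoids = cl$medoid_ids,
                           total_cost = cl$total_cost,
                           silhouette = cl$silhouette,
                           stability = cl$stability)
  }
  out
}
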