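## Known configuration keys per block; unknown keys are rejected outright.
.CONFIG_KEYS <- list(
  top = c("scm", "trials", "thresholds", "bootstrap", "output_dir", "seed",
          "grid", "make_plots", "model"),
  bootstrap = c("n_resamples", "cluster_unit", "mode")
)

#' Read and validate a pipeline run configuration
#'
#' The configuration is YAML with strict parsing: unknown keys anywhere are
#' an error.  Structure:
#' \preformatted{
#' scm:            # scenario name plus scm_params() overrides
#'   scenario: baseline
#'   n_patients: 2000
#' trials: [1, 2, 3, 4]
#' thresholds: [1.5, 3, 6]    # sensitivity thresholds for trials 3-4
#' bootstrap: {n_resamples: 1000, cluster_unit: hospital}
#' model: {surgeon_form: spline}   # optional emulation_spec model overrides
#' output_dir: results
#' seed: 1
#' }
#'
#' @param path YAML file path, or a list with the same structure.
#' @return Validated configuration list of class `volemu_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS$top)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$trials <- as.integer(cfg$trials %||% 1:4)
  if (!all(cfg$trials %in% 1:4)) stop("trials must be in 1..4", call. = FALSE)
  cfg$thresholds <- cfg$thresholds %||% 1.5
  cfg$grid <- cfg$grid %||% "report"
  cfg$make_plots <- isTRUE(cfg$make_plots)
  cfg$output_dir <- cfg$output_dir %||% "volemu-results"
  scm <- cfg$scm %||% list()
  scen <- scm$scenario %||% "baseline"
  over <- scm[setdiff(names(scm), "scenario")]
  known <- names(formals(scm_params))
  bad <- setdiff(names(over), known)
  if (length(bad)) {
    stop("unknown scm key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg$params <- do.call(scm_scenario,
                        c(list(name = scen), over,
                          list(seed = sub_seed(cfg$seed, "simulate"))))
  bc <- cfg$bootstrap %||% list()
  badb <- setdiff(names(bc), .CONFIG_KEYS$bootstrap)
  if (length(badb)) {
    stop("unknown bootstrap key(s): ", paste(badb, collapse = ", "),
         call. = FALSE)
  }
  cfg$bootstrap <- do.call(bootstrap_config,
                           c(bc, list(seed = sub_seed(cfg$seed, "bootstrap"))))
  structure(cfg, class = "volemu_config")
}

#' Run the full simulate - emulate - bootstrap - report pipeline
#'
#' Executes every configured trial (and, for trials 3-4, every sensitivity
#' driving-time threshold), writing claims CSVs, arm assignments, risk grids
#' with cluster-bootstrap CIs, an oracle-comparison report (estimate minus
#' true counterfactual risk per arm) and a manifest with seeds, package
#' version and a content hash of every numeric output.  Stage boundaries are
#' logged with patient and cluster counts; a failing stage leaves a
#' stage-labelled entry in `error_log.txt` while completed outputs are kept.
#'
#' @param config path to a YAML configuration or a configuration list
#'   (see [read_run_config()]).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "volemu_config")) config else
    read_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(cfg$output_dir, "error_log.txt")
  if (file.exists(log_file)) unlink(log_file)
  artifacts <- character()
  fail <- function(stage, e) {
    cat(sprintf("[%s] %s\n", stage, conditionMessage(e)), file = log_file,
        append = TRUE)
    warning(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            call. = FALSE)
    NULL
  }

  message(sprintf("simulate: %d patients, %d surgeons, %d hospitals",
                  cfg$params$n_patients, cfg$params$n_surgeons,
                  cfg$params$n_hospitals))
  claims <- tryCatch(simulate_claims(cfg$params),
                     error = function(e) fail("simulate", e))
  if (is.null(claims)) return(invisible(NULL))
  artifacts <- c(artifacts, write_claims(claims, file.path(cfg$output_dir,
                                                           "claims")))

  specs <- list()
  for (tr in cfg$trials) {
    ths <- if (tr >= 3) cfg$thresholds else NA
    for (th in ths) {
      sp <- emulation_spec(tr,
                           travel_threshold_hours = if (!is.na(th)) th else 1.5,
                           model = cfg$model %||% list())
      tag <- if (tr >= 3) sprintf("trial%d_%gh", tr, th) else
        sprintf("trial%d", tr)
      specs[[tag]] <- sp
    }
  }

  all_grids <- list()
  for (tag in names(specs)) {
    sp <- specs[[tag]]
    message(sprintf("emulate %s: %d arms", tag, n_arms(sp)))
    res <- tryCatch({
      cohort <- build_cohort(claims, sp)
      arms <- assign_arms(apply_eligibility(claims$patients), claims, sp)
      f_arm <- file.path(cfg$output_dir, sprintf("arms_%s.csv", tag))
      write.csv(arms, f_arm, row.names = FALSE)
      message(sprintf("  cohort: %d eligible patients, %d beyond threshold",
                      nrow(cohort), sum(cohort$beyond_threshold)))
      grid <- cluster_bootstrap(claims, sp, cfg$bootstrap, grid = cfg$grid)
      f_grid <- file.path(cfg$output_dir, sprintf("risks_%s.csv", tag))
      write.csv(.grid_df(grid), f_grid, row.names = FALSE)
      artifacts <- c(artifacts, f_arm, f_grid)
      all_grids[[tag]] <- grid
      grid
    }, error = function(e) fail(tag, e))
  }

  ## oracle comparison: estimate vs true counterfactual risk per arm
  orc <- tryCatch({
    rows <- list()
    for (tag in names(all_grids)) {
      g <- all_grids[[tag]]
      sp <- attr(g, "spec")
      for (i in seq_len(nrow(g))) {
        a <- arm_spec(g$surgeon_volume_arm[i],
                      if (sp$trial >= 2) g$hospital_volume_arm[i],
                      threshold_hours = sp$travel_threshold_hours)
        truth <- true_counterfactual_risk(cfg$params, a, claims,
                                          n_mc = 400L,
                                          seed = sub_seed(cfg$seed, "oracle"))
        rows[[length(rows) + 1L]] <- data.frame(
          design = tag, surgeon_volume_arm = g$surgeon_volume_arm[i],
          hospital_volume_arm = g$hospital_volume_arm[i],
          estimate = g$risk[i], truth = truth, bias = g$risk[i] - truth)
      }
    }
    df <- do.call(rbind, rows)
    f <- file.path(cfg$output_dir, "oracle_comparison.csv")
    write.csv(df, f, row.names = FALSE)
    artifacts <- c(artifacts, f)
    df
  }, error = function(e) fail("oracle-comparison", e))

  rep_files <- tryCatch(render_report(cfg$output_dir, all_grids,
                                      make_plots = cfg$make_plots),
                        error = function(e) fail("report", e))
  artifacts <- c(artifacts, rep_files)

  manifest <- list(
    package_version = as.character(packageVersion("volemu")),
    seed = cfg$seed,
    substreams = list(simulate = sub_seed(cfg$seed, "simulate"),
                      bootstrap = sub_seed(cfg$seed, "bootstrap"),
                      oracle = sub_seed(cfg$seed, "oracle")),
    n_patients = nrow(claims$patients),
    files = lapply(setNames(nm = sort(unique(artifacts))), function(f) {
      list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("done: %d artifacts in %s", length(manifest$files),
                  cfg$output_dir))
  invisible(manifest)
}

#' @keywords internal
.grid_df <- function(g) {
  cols <- intersect(c("trial", "surgeon_volume_arm", "hospital_volume_arm",
                      "risk", "ci_lower", "ci_upper", "risk_difference",
                      "rd_ci_lower", "rd_ci_upper", "is_reference"),
                    names(g))
  as.data.frame(g)[, cols]
}

#' Render tabular and graphical summaries of a result bundle
#'
#' Produces a wide CSV mirroring the published table's layout (hospital
#' strata by trial, surgeon-volume columns with estimates and risk
#' differences plus 95% CIs) and a long-format CSV of risk-vs-surgeon-volume
#' curves restricted to the 5th-95th percentile of observed surgeon volume
#' (for plotting).  Grids lacking bootstrap CI columns are rendered as point
#' estimates with a prominent warning.  Plots are drawn with ggplot2 when
#' available and requested.
#'
#' @param output_dir directory to write into.
#' @param grids named list of `volemu_risk_grid` objects (as produced inside
#'   [run_pipeline()]); names label the designs.
#' @param make_plots draw PDF figures (requires ggplot2)?
#' @return Character vector of files written.
#' @export
render_report <- function(output_dir, grids, make_plots = FALSE) {
  files <- character()
  fmt_ci <- function(est, lo, hi, pct = TRUE) {
    k <- if (pct) 100 else 100  # risks and RDs both reported in percent units
    if (is.null(lo)) return(sprintf("%.1f", k * est))
    sprintf("%.1f (%.1f to %.1f)", k * est, k * lo, k * hi)
  }
  rows <- list()
  for (tag in names(grids)) {
    g <- grids[[tag]]
    if (is.null(g$ci_lower)) {
      warning(sprintf("grid '%s' has no bootstrap CIs; reporting point estimates only",
                      tag), call. = FALSE)
    }
    strata <- unique(ifelse(is.na(g$hospital_volume_arm), "natural",
                            as.character(g$hospital_volume_arm)))
    for (st in strata) {
      sel <- (is.na(g$hospital_volume_arm) & st == "natural") |
        (!is.na(g$hospital_volume_arm) & as.character(g$hospital_volume_arm) == st)
      gs <- g[sel, ]
      gs <- gs[order(gs$surgeon_volume_arm), ]
      est <- vapply(seq_len(nrow(gs)), function(i)
        fmt_ci(gs$risk[i], gs$ci_lower[i], gs$ci_upper[i]), character(1))
      rd <- vapply(seq_len(nrow(gs)), function(i) {
        if (gs$is_reference[i]) "Reference" else
          fmt_ci(gs$risk_difference[i], gs$rd_ci_lower[i], gs$rd_ci_upper[i])
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        hospital_stratum = st, design = tag, quantity = "estimate_pct",
        t(setNames(est, paste0("surgeon_", gs$surgeon_volume_arm))),
        check.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        hospital_stratum = st, design = tag, quantity = "risk_difference_pp",
        t(setNames(rd, paste0("surgeon_", gs$surgeon_volume_arm))),
        check.names = FALSE)
    }
  }
  if (length(rows)) {
    tab <- do.call(rbind, rows)
    f <- file.path(output_dir, "table_risks.csv")
    write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }

  ## long format for figure-style curves, 5th-95th pct of observed volume
  long <- do.call(rbind, lapply(names(grids), function(tag) {
    g <- grids[[tag]]
    cohort <- attr(g, "cohort")
    q <- if (!is.null(cohort)) {
      quantile(cohort$surgeon_volume, c(0.05, 0.95), type = 1)
    } else range(g$surgeon_volume_arm)
    d <- .grid_df(g)
    d$design <- tag
    d[d$surgeon_volume_arm >= q[1] & d$surgeon_volume_arm <= q[2], ]
  }))
  if (!is.null(long) && nrow(long)) {
    f <- file.path(output_dir, "figure_curves.csv")
    write.csv(long, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (make_plots && requireNamespace("ggplot2", quietly = TRUE) &&
      !is.null(long) && nrow(long)) {
    gp <- ggplot2::ggplot(long, ggplot2::aes(
      x = surgeon_volume_arm, y = 100 * risk,
      colour = factor(hospital_volume_arm))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~design) +
      ggplot2::labs(x = "Surgeon annual volume (operations/y)",
                    y = "Standardized 90-day mortality (%)",
                    colour = "Hospital volume") +
      ggplot2::theme_minimal()
    f <- file.path(output_dir, "figure_curves.pdf")
    ggplot2::ggsave(f, gp, width = 9, height = 6)
    files <- c(files, f)
  }
  files
}
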