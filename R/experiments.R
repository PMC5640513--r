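#' Run the guard-cell model scenario matrix
#'
#' Solves the five model variants on identical load protocols - baseline,
#' VWT (rounded-triangular section), VWT with the ventral wall thickness
#' scaled by +/-10%, and baseline with fixed poles - and tabulates their
#' aperture-pressure curves, opening thresholds, final apertures, and the
#' curve-level ordering checks the variants are expected to satisfy.
#'
#' @param geometry Base [geometry_params()] (circular section; the VWT
#'   variants switch `cross_section_kind` internally).
#' @param material A [material_params()] object.
#' @param protocol A [load_protocol()].
#' @param options [solver_options()].
#' @param epi_patches Epidermal pressure surface set.
#' @param variants Character subset of
#'   `c("baseline", "vwt", "vwt_plus10", "vwt_minus10", "fixed_poles")`.
#' @param verbose Print progress?
#' @return A list of class `gc_scenario_report`: `curves` (one tibble,
#'   with a `variant` column), `summary` (per-variant threshold, plateau,
#'   final aperture, length change), `checks` (pass/fail tibble) and the
#'   solutions.
#' @export
run_scenario_matrix <- function(geometry = geometry_params(),
                                material = material_params(),
                                protocol = load_protocol(),
                                options = solver_options(),
                                epi_patches = c("dorsal", "periclinal_outer",
                                                "periclinal_inner"),
                                variants = c("baseline", "vwt", "vwt_plus10",
                                             "vwt_minus10", "fixed_poles"),
                                verbose = FALSE) {
  specs <- list(
    baseline = list(kind = "circular", m_v = 1, fixed = FALSE),
    vwt = list(kind = "rounded_triangular", m_v = 1, fixed = FALSE),
    vwt_plus10 = list(kind = "rounded_triangular", m_v = 1.1, fixed = FALSE),
    vwt_minus10 = list(kind = "rounded_triangular", m_v = 0.9, fixed = FALSE),
    fixed_poles = list(kind = "circular", m_v = 1, fixed = TRUE)
  )[variants]
  sols <- list(); curves <- list(); fails <- character(0)
  for (v in names(specs)) {
    sp <- specs[[v]]
    gp <- geometry
    gp$cross_section_kind <- sp$kind
    gp$m_v <- sp$m_v
    if (verbose) message("solving variant: ", v)
    mesh <- build_geometry(gp)
    sol <- try(solve_quasistatic(mesh, material, protocol,
                                 fixed_poles = sp$fixed, options = options,
                                 epi_patches = epi_patches),
               silent = TRUE)
    if (inherits(sol, "try-error")) {
      fails <- c(fails, v)
      warning("variant ", v, " failed: ", attr(sol, "condition")$message)
      next
    }
    sols[[v]] <- sol
    curves[[v]] <- dplyr::mutate(aperture_curve(sol), variant = v)
  }
  curves_tb <- dplyr::bind_rows(curves)
  summary <- purrr::map_dfr(names(sols), function(v) {
    cv <- curves[[v]]
    tibble::tibble(
      variant = v,
      threshold = opening_threshold(cv),
      plateau = plateau_onset(cv),
      final_aperture = cv$aperture[nrow(cv)],
      max_aperture = max(cv$aperture),
      length_change_rel = max(abs(cv$complex_length - cv$complex_length[1])) /
        cv$complex_length[1]
    )
  })
  checks <- scenario_checks(curves, summary)
  out <- list(curves = curves_tb, summary = summary, checks = checks,
              solutions = sols, failed_variants = fails,
              material = material, protocol = protocol)
  class(out) <- "gc_scenario_report"
  out
}

scenario_checks <- function(curves, summary) {
  have <- function(...) all(c(...) %in% names(curves))
  rows <- list()
  add <- function(name, pass, detail) {
    rows[[length(rows) + 1]] <<- tibble::tibble(check = name, pass = pass,
                                                detail = detail)
  }
  g <- function(v, col = "aperture") curves[[v]][[col]]
  if (have("baseline", "fixed_poles")) {
    thr_b <- summary$threshold[summary$variant == "baseline"]
    thr_f <- summary$threshold[summary$variant == "fixed_poles"]
    add("fixed_poles opens at lower pressure", isTRUE(thr_f < thr_b),
        sprintf("threshold %.3g vs baseline %.3g MPa", thr_f, thr_b))
    add("fixed_poles attains larger final aperture",
        isTRUE(max(g("fixed_poles")) > max(g("baseline"))),
        sprintf("max aperture %.3g vs %.3g um",
                max(g("fixed_poles")), max(g("baseline"))))
    add("fixed_poles complex length constant",
        summary$length_change_rel[summary$variant == "fixed_poles"] < 1e-3,
        sprintf("relative length change %.2g",
                summary$length_change_rel[summary$variant == "fixed_poles"]))
  }
  if (have("baseline")) {
    cb <- curves[["baseline"]]
    above1 <- cb$P_gc >= 1
    add("baseline complex length increases above 1 MPa",
        isTRUE(utils::tail(cb$complex_length, 1) >
                 cb$complex_length[which(above1)[1]] + 0.1),
        sprintf("length %.4g -> %.4g um",
                cb$complex_length[which(above1)[1]],
                utils::tail(cb$complex_length, 1)))
  }
  if (have("baseline", "vwt")) {
    cb <- curves[["baseline"]]; cv <- curves[["vwt"]]
    opening <- cb$P_gc > max(cb$P_epi) & cb$P_gc < 3
    late <- cb$P_gc >= 0.8 * max(cb$P_gc)
    add("VWT larger aperture at low pressure",
        isTRUE(max((cv$aperture - cb$aperture)[opening]) > 0),
        sprintf("max low-P difference %.3g um",
                max((cv$aperture - cb$aperture)[opening])))
    add("VWT smaller aperture at high pressure",
        isTRUE(mean((cv$aperture - cb$aperture)[late]) < 0),
        sprintf("mean high-P difference %.3g um",
                mean((cv$aperture - cb$aperture)[late])))
  }
  if (have("vwt", "vwt_plus10", "vwt_minus10")) {
    rng <- diff(range(g("vwt")))
    dev <- max(abs(g("vwt_plus10") - g("vwt_minus10"))) / rng
    add("VWT +/-10% inner thickness curves superimposed (< 2% of range)",
        isTRUE(dev < 0.02), sprintf("max |difference| = %.3g of range", dev))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.gc_scenario_report <- function(x, ...) {
  cat("<gc_scenario_report>\n")
  print(as.data.frame(x$summary), digits = 3)
  cat("\nchecks:\n")
  print(as.data.frame(x$checks))
  if (length(x$failed_variants)) {
    cat("failed variants:", paste(x$failed_variants, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the synthetic AFM recovery study
#'
#' Generates `n_mature` mature-preset and `n_young` young-preset force
#' maps with distinct seeds and randomized stoma poses, processes each
#' into an apparent-modulus map, extracts the diameter transect, computes
#' the per-stoma stiffness-gradient statistic, and compares the two
#' gradient samples with a two-sided Mann-Whitney test.
#'
#' @param n_mature,n_young Numbers of maps per stage.
#' @param seed Base seed; map `m` of each stage uses `seed + m - 1`
#'   (mature) and `seed + 1000 + m - 1` (young).
#' @param cfg An [afm_config()]. The default uses a 40 um per-stoma field
#'   at the full 128 x 128 grid: transect profiling of sub-micrometre wall
#'   ridges needs the close-up pixel pitch (about 0.3 um), as in
#'   stoma-level force maps; 100 um overview maps undersample the paired
#'   wall ridges.
#' @param noise_args Overrides passed to [noise_model()] (besides the
#'   seed).
#' @param verbose Print progress?
#' @return A list of class `gc_afm_study`: `gradients` tibble (stage,
#'   seed, gradient, flag), `median_mature`, `median_young`, `test`
#'   (the `mw_test`), and exclusion counts.
#' @export
run_afm_study <- function(n_mature = 14, n_young = 18, seed = 1,
                          cfg = afm_config(map_size = 40), noise_args = list(),
                          verbose = FALSE) {
  one <- function(stage, sd_off, m) {
    sd <- seed + sd_off + m - 1
    set.seed(sd + 500000L)
    # random pose: centre jitter and free orientation
    pose_ctr <- cfg$map_size / 2 + stats::runif(2, -2, 2)
    pose_th <- stats::runif(1, 0, pi)
    gt <- make_ground_truth(stage, pose = list(
      center = pose_ctr,
      axes = if (stage == "mature") c(12, 6.5) else c(6, 5.5),
      orientation = pose_th
    ), map_size = cfg$map_size)
    nm <- do.call(noise_model, c(list(seed = sd), noise_args))
    fm <- simulate_force_map(gt, cfg, nm)
    em <- suppressWarnings(process_force_map(fm))
    prof <- extract_transect(em, gt$pose, mode = "diameter")
    gr <- gradient_statistic(prof)
    if (verbose) {
      message(sprintf("%s map %d (seed %d): gradient %s", stage, m, sd,
                      format(gr$gradient, digits = 3)))
    }
    tibble::tibble(stage = stage, map = m, seed = sd,
                   gradient = gr$gradient, n_peaks = gr$n_peaks,
                   flag = gr$flag)
  }
  res <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_mature), function(m) one("mature", 0L, m)),
    purrr::map_dfr(seq_len(n_young), function(m) one("young", 1000L, m))
  )
  gm <- res$gradient[res$stage == "mature" & res$flag == "ok"]
  gy <- res$gradient[res$stage == "young" & res$flag == "ok"]
  test <- if (length(gm) && length(gy)) mann_whitney_u(gm, gy) else NULL
  out <- list(gradients = res,
              median_mature = stats::median(gm),
              median_young = stats::median(gy),
              n_excluded = sum(res$flag != "ok"),
              test = test, seed = seed, cfg = cfg)
  class(out) <- "gc_afm_study"
  out
}

#' @export
print.gc_afm_study <- function(x, ...) {
  cat("<gc_afm_study>\n")
  cat(sprintf("  mature: median gradient %.3g MPa/um (n = %d)\n",
              x$median_mature,
              sum(x$gradients$stage == "mature" & x$gradients$flag == "ok")))
  cat(sprintf("  young:  median gradient %.3g MPa/um (n = %d)\n",
              x$median_young,
              sum(x$gradients$stage == "young" & x$gradients$flag == "ok")))
  if (x$n_excluded) cat(sprintf("  %d maps excluded (peaks not detected)\n", x$n_excluded))
  if (!is.null(x$test)) {
    cat(sprintf("  Mann-Whitney U = %g, two-sided p = %.3g\n",
                x$test$U, x$test$p_value))
  }
  invisible(x)
}

#' Write scenario or AFM study results to CSV/JSON files
#'
#' @param report A `gc_scenario_report` or `gc_afm_study`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (inherits(report, "gc_scenario_report")) {
    p1 <- file.path(dir, "aperture_curves.csv")
    utils::write.csv(report$curves, p1, row.names = FALSE)
    p2 <- file.path(dir, "scenario_summary.csv")
    utils::write.csv(report$summary, p2, row.names = FALSE)
    p3 <- file.path(dir, "scenario_checks.json")
    jsonlite::write_json(report$checks, p3, pretty = TRUE)
    paths <- c(p1, p2, p3)
  } else if (inherits(report, "gc_afm_study")) {
    p1 <- file.path(dir, "gradients.csv")
    utils::write.csv(report$gradients, p1, row.names = FALSE)
    p2 <- file.path(dir, "afm_study.json")
    jsonlite::write_json(list(median_mature = report$median_mature,
                              median_young = report$median_young,
                              U = report$test$U, p_value = report$test$p_value,
                              n_excluded = report$n_excluded,
                              seed = report$seed),
                         p2, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths <- c(p1, p2)
  } else stop("unknown report type")
  invisible(paths)
}
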