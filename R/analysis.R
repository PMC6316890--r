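#' Ligament-deficiency scenario study and statistics
#'
#' Orchestrates the four ligament conditions (intact, isolated MCL
#' anterior-bundle deficiency, isolated MCL posterior-bundle deficiency,
#' complete MCL deficiency) under the identical drive, builds the
#' kinematic-difference and peak-load comparison tables, and runs the
#' statistical procedure: one-way ANOVA with ligament state as the factor
#' over the 40 flexion-grid samples per condition, followed by
#' Tukey-Kramer pairwise comparisons of each deficient condition against
#' the intact elbow, with significance at p <= 0.01.
#'
#' The 40 grid points of one condition are serially correlated along the
#' flexion arc; treating them as independent samples overstates the
#' statistical evidence. The procedure is reproduced in that form
#' deliberately, and reports carry this caveat.
#'
#' @name deficiency-analysis
NULL

SCENARIOS <- c("intact", "MCL_AB_deficient", "MCL_PB_deficient",
               "both_MCL_deficient")

#' One-way analysis of variance
#'
#' Classic between/within sum-of-squares decomposition computed from the
#' defining formulas; the p-value comes from the F distribution.
#'
#' @param groups list of (>= 2) numeric vectors, each with >= 2 samples.
#' @return list with `F`, `p`, `df` (numerator, denominator), `ss_between`,
#'   `ss_within`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  n <- vapply(groups, length, 0L)
  if (any(n < 2)) stop("each group needs at least two samples")
  m <- vapply(groups, mean, 0)
  gm <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  dfb <- length(groups) - 1
  dfw <- sum(n) - length(groups)
  if (ssw == 0) {
    if (ssb <= 1e-300) return(list(F = 0, p = 1, df = c(dfb, dfw),
                                   ss_between = ssb, ss_within = ssw))
    return(list(F = Inf, p = 0, df = c(dfb, dfw),
                ss_between = ssb, ss_within = ssw))
  }
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, p = stats::pf(Fv, dfb, dfw, lower.tail = FALSE),
       df = c(dfb, dfw), ss_between = ssb, ss_within = ssw)
}

#' Tukey-Kramer pairwise comparison
#'
#' Studentized-range statistic for every pair with the Kramer
#' unequal-sample-size correction,
#' `q = |m_i - m_j| / sqrt(s2/2 (1/n_i + 1/n_j))`, with p-values from the
#' studentized range distribution. With equal group sizes the Kramer
#' correction reduces to the standard Tukey HSD.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level (default 0.01).
#' @return list with `p` (symmetric matrix of pairwise p-values), `q`
#'   (statistics), `significant` (logical matrix at `alpha`).
#' @export
tukey_kramer <- function(groups, alpha = 0.01) {
  if (!is.list(groups) || length(groups) < 2)
    stop("Tukey-Kramer needs at least two groups")
  k <- length(groups)
  nm <- names(groups) %||% paste0("g", seq_len(k))
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  dfw <- sum(n) - k
  s2 <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0)) / dfw
  P <- Q <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { P[i, j] <- 1; Q[i, j] <- 0; next }
    if (s2 <= 0) {
      Q[i, j] <- if (m[i] == m[j]) 0 else Inf
      P[i, j] <- if (m[i] == m[j]) 1 else 0
      next
    }
    q <- abs(m[i] - m[j]) / sqrt(s2 / 2 * (1 / n[i] + 1 / n[j]))
    Q[i, j] <- q
    P[i, j] <- stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
  }
  list(p = P, q = Q, significant = P <= alpha)
}

#' Run the four-scenario deficiency study
#'
#' Runs the intact elbow first, then each requested deficiency with the
#' identical drive and parameters. Per-scenario results are cached to
#' disk (keyed by an MD5 of the full configuration) so re-running the
#' same study reuses completed scenarios.
#'
#' @param geometry an `elbow_geometry`.
#' @param scenarios character vector of scenario names (see `SCENARIOS`).
#' @param drive a [motion_drive()].
#' @param sim_config a [simulation_config()].
#' @param contact contact parameter list as in [assemble_system()].
#' @param loads an [external_loads()].
#' @param grid flexion sampling grid `c(start, stop, step)`, degrees.
#' @param cache_dir directory for cached scenario results (`NULL`
#'   disables caching).
#' @return list of `scenario_result` objects, named by scenario.
#' @export
run_study <- function(geometry,
                      scenarios = SCENARIOS,
                      drive = motion_drive(),
                      sim_config = simulation_config(),
                      contact = list(uh = contact_parameters(kc = 126),
                                     rh = contact_parameters(kc = 105)),
                      loads = external_loads(),
                      grid = c(50, 130, 2),
                      cache_dir = NULL) {
  bad <- setdiff(scenarios, SCENARIOS)
  if (length(bad))
    stop("unknown scenario(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(SCENARIOS, collapse = ", "))
  scenarios <- unique(c(intersect("intact", scenarios),
                        setdiff(scenarios, "intact")))
  key <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    key <- config_hash(list(geometry$config, drive, sim_config, contact,
                            loads, grid))
  }
  results <- list()
  failed <- character(0)
  for (sc in scenarios) {
    cache_file <- if (!is.null(key))
      file.path(cache_dir, paste0(sc, "_", key, ".rds")) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      results[[sc]] <- readRDS(cache_file)
      next
    }
    res <- tryCatch({
      atlas <- section_bundles(geometry$atlas, sc)
      sys <- assemble_system(geometry, atlas = atlas, contact = contact,
                             loads = loads)
      trace <- run_flexion_sim(sys, drive, sim_config)
      summarize_scenario(sys, trace, sc, grid)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, paste0(sc, " (", conditionMessage(res), ")"))
      next
    }
    results[[sc]] <- res
    if (!is.null(cache_file)) saveRDS(res, cache_file)
  }
  if (length(failed))
    stop("study incomplete; failed scenario(s): ",
         paste(failed, collapse = "; "),
         if (length(results)) paste0("; completed: ",
                                     paste(names(results), collapse = ", ")))
  results
}

config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# condense one scenario run into the result structure the reports consume
summarize_scenario <- function(sys, trace, scenario, grid = c(50, 130, 2)) {
  su <- resample_by_flexion(trace, grid[1], grid[2], grid[3], body = "ulna")
  sr <- resample_by_flexion(trace, grid[1], grid[2], grid[3], body = "radius")
  nstep <- nrow(trace$steps)
  csum <- do.call(rbind, lapply(seq_len(nstep), function(i) {
    cd <- trace$contact[[i]]
    out <- do.call(rbind, lapply(split(cd, cd$region), function(d) {
      # medial sub-compartment: elements medial (more negative map v)
      # than the trochlear groove centre
      med <- d$v < -13
      data.frame(region = d$region[1],
                 peak_pressure = max(d$pressure),
                 contact_area = sum(d$area[d$delta > 0]),
                 frac_contact = mean(d$delta > 0),
                 medial_frac = if (any(med)) mean(d$delta[med] > 0)
                 else NA_real_)
    }))
    out$step <- i
    out$flexion <- trace$steps$flexion[i]
    out
  }))
  lsum <- do.call(rbind, lapply(seq_len(nstep), function(i) {
    ld <- trace$ligament[[i]]
    ag <- stats::aggregate(cbind(force = ld$force) ~ complex, data = ld, sum)
    mx <- stats::aggregate(cbind(strain = ifelse(is.na(ld$strain), -Inf,
                                                 ld$strain)) ~ complex,
                           data = ld, max)
    m <- merge(ag, mx, by = "complex")
    m$active <- vapply(split(ld$active, ld$complex)[m$complex], any, TRUE)
    m$step <- i; m$flexion <- trace$steps$flexion[i]
    m
  }))
  peaks <- do.call(rbind, lapply(split(lsum, lsum$complex), function(d) {
    data.frame(complex = d$complex[1],
               active = any(d$active),
               peak_load = if (any(d$active)) max(d$force) else NA_real_,
               max_strain = if (any(d$active))
                 max(d$strain[is.finite(d$strain)]) else NA_real_)
  }))
  row.names(peaks) <- NULL
  structure(list(
    scenario = scenario,
    samples_ulna = su, samples_radius = sr,
    contact_summary = csum,
    peak_pressure = max(csum$peak_pressure),
    ligament_summary = lsum,
    ligament_peaks = peaks,
    dislocation = dislocation_flags(csum),
    steps = trace$steps,
    grid = grid
  ), class = "scenario_result")
}

# dislocation candidate: >90% of one compartment's elements out of contact
# over a contiguous flexion span of more than 10 degrees
dislocation_flags <- function(csum) {
  out <- list()
  for (rg in unique(csum$region)) {
    d <- csum[csum$region == rg, ]
    d <- d[order(d$step), ]
    lost <- d$frac_contact < 0.10
    span <- 0; flag <- FALSE; runs <- rle(lost)
    if (any(runs$values)) {
      ends <- cumsum(runs$lengths)
      starts <- c(1, utils::head(ends, -1) + 1)
      for (i in which(runs$values)) {
        fl <- d$flexion[starts[i]:ends[i]]
        span_i <- max(fl) - min(fl)
        span <- max(span, span_i)
        if (span_i > 10) flag <- TRUE
      }
    }
    out[[rg]] <- list(flag = flag, max_lost_span = span)
  }
  out
}

#' Study-level kinematic statistics
#'
#' Per body and degree of freedom: one-way ANOVA over all conditions'
#' flexion-grid samples, and Tukey-Kramer p-values of each deficient
#' condition against intact.
#'
#' @param results named list from [run_study()] (must include `intact`).
#' @param alpha significance level (default 0.01).
#' @return data.frame: body, dof, scenario, mean_diff, sd_diff, F, p_anova,
#'   p_tukey, significant.
#' @export
study_statistics <- function(results, alpha = 0.01) {
  if (!"intact" %in% names(results))
    stop("statistics require the intact baseline scenario")
  dofs <- c("IE", "VV", "SI", "AP", "ML")
  out <- list()
  for (body in c("ulna", "radius")) {
    fld <- paste0("samples_", body)
    for (dof in dofs) {
      groups <- lapply(results, function(r) r[[fld]][[dof]])
      an <- one_way_anova(groups)
      tk <- tukey_kramer(groups, alpha = alpha)
      for (sc in setdiff(names(results), "intact")) {
        dd <- difference_vs_intact(results[[sc]][[fld]],
                                   results$intact[[fld]])
        srow <- dd$summary[dd$summary$dof == dof, ]
        out[[length(out) + 1L]] <- data.frame(
          body = body, dof = dof, scenario = sc,
          mean_diff = srow$mean, sd_diff = srow$sd,
          F = an$F, p_anova = an$p,
          p_tukey = tk$p["intact", sc],
          significant = tk$p["intact", sc] <= alpha)
      }
    }
  }
  do.call(rbind, out)
}

#' Build the study report bundle
#'
#' Assembles (a) mean kinematic difference +/- SD tables with Tukey-Kramer
#' p-values per body (one row per deficient condition and DOF), (b) peak
#' ligament load / max strain tables with sectioned complexes rendered as
#' missing values, (c) per-scenario kinematic curves against flexion, and
#' (d) contact pressure maps at selected flexion angles. With `dir` given,
#' everything is also written as CSV plus a JSON summary; regeneration
#' from the same results is byte-identical.
#'
#' @param results named list from [run_study()].
#' @param stats result of [study_statistics()] (computed if `NULL`).
#' @param dir optional output directory.
#' @param map_flexions flexion angles (degrees) at which contact maps are
#'   extracted.
#' @return list with `kinematic_table`, `ligament_table`, `curves`,
#'   `contact_maps`, `peak_pressures`, `dislocation`, `note`.
#' @export
build_report <- function(results, stats = NULL, dir = NULL,
                         map_flexions = c(60, 90, 120)) {
  if (!"intact" %in% names(results))
    stop("report requires the intact baseline scenario (kinematic ",
         "differences are undefined without it)")
  if (is.null(stats)) stats <- study_statistics(results)
  lig <- do.call(rbind, lapply(names(results), function(sc) {
    p <- results[[sc]]$ligament_peaks
    p$scenario <- sc
    p
  }))
  curves <- do.call(rbind, lapply(names(results), function(sc) {
    rbind(transform(results[[sc]]$samples_ulna, scenario = sc),
          transform(results[[sc]]$samples_radius, scenario = sc))
  }))
  # contact maps come from the contact summaries retained per scenario
  maps <- do.call(rbind, lapply(names(results), function(sc) {
    cs <- results[[sc]]$contact_summary
    do.call(rbind, lapply(map_flexions, function(fl) {
      d <- cs[abs(cs$flexion - fl) == min(abs(cs$flexion - fl)), ]
      d$at_flexion <- fl; d$scenario <- sc; d
    }))
  }))
  peaks <- data.frame(
    scenario = names(results),
    peak_pressure = vapply(results, function(r) r$peak_pressure, 0),
    row.names = NULL)
  disl <- data.frame(
    scenario = rep(names(results), each = 2),
    compartment = unlist(lapply(results, function(r) names(r$dislocation))),
    flag = unlist(lapply(results, function(r)
      vapply(r$dislocation, function(x) x$flag, TRUE))),
    max_lost_span = unlist(lapply(results, function(r)
      vapply(r$dislocation, function(x) x$max_lost_span, 0))),
    row.names = NULL)
  note <- paste("Flexion-grid samples are serially correlated;",
                "the ANOVA/Tukey-Kramer procedure treats them as",
                "independent, so p-values overstate the evidence.")
  rep <- list(kinematic_table = stats, ligament_table = lig,
              curves = curves, contact_maps = maps,
              peak_pressures = peaks, dislocation = disl, note = note)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(d, f) utils::write.csv(
      d, file.path(dir, f), row.names = FALSE)
    wcsv(stats, "kinematic_differences.csv")
    wcsv(lig, "ligament_peaks.csv")
    wcsv(curves, "kinematic_curves.csv")
    wcsv(maps, "contact_maps.csv")
    wcsv(peaks, "peak_pressures.csv")
    wcsv(disl, "dislocation_flags.csv")
    jsonlite::write_json(
      list(scenarios = names(results),
           peak_pressures = stats::setNames(as.list(peaks$peak_pressure),
                                            peaks$scenario),
           dislocation_flags = stats::setNames(as.list(disl$flag),
                                               paste(disl$scenario,
                                                     disl$compartment)),
           note = note),
      file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  rep
}
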