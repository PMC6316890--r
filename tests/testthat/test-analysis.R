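# ANOVA, Tukey-Kramer, report structure

test_that("one-way ANOVA matches hand computation and edge conventions", {
  # identical groups: F = 0, p = 1
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  r <- one_way_anova(g)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  # hand-computed: (1,2,3) vs (4,5,6): SSB = 13.5, SSW = 4, df = 1, 4
  r2 <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r2$ss_between, 13.5)
  expect_equal(r2$ss_within, 4)
  expect_equal(r2$F, 13.5)
  # zero within-group variance with unequal means
  r3 <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(r3$p, 0)
  expect_error(one_way_anova(list(1:3)), "two groups")
  expect_error(one_way_anova(list(1:3, 2)), "two samples")
})

test_that("ANOVA agrees with the reference implementation on random data", {
  set.seed(99)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i)
      rnorm(sample(4:12, 1), mean = runif(1, -1, 1)))
    mine <- one_way_anova(groups)
    dat <- data.frame(y = unlist(groups),
                      g = factor(rep(seq_len(k),
                                     vapply(groups, length, 0L))))
    ref <- summary(stats::aov(y ~ g, data = dat))[[1]]
    expect_equal(mine$F, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("Tukey-Kramer agrees with the reference implementation", {
  set.seed(100)
  for (rep in 1:6) {
    # unequal group sizes exercise the Kramer correction
    ns <- sample(5:12, 4, replace = TRUE)
    groups <- lapply(ns, function(n) rnorm(n, mean = runif(1, -1, 1)))
    names(groups) <- paste0("g", 1:4)
    mine <- tukey_kramer(groups)
    dat <- data.frame(y = unlist(groups),
                      g = factor(rep(names(groups), ns)))
    ref <- stats::TukeyHSD(stats::aov(y ~ g, data = dat))$g
    for (row in rownames(ref)) {
      ij <- strsplit(row, "-")[[1]]
      expect_equal(mine$p[ij[1], ij[2]], ref[row, "p adj"],
                   tolerance = 1e-6)
    }
  }
})

test_that("equal sample sizes reduce Kramer to the standard Tukey q", {
  set.seed(101)
  groups <- lapply(1:3, function(i) rnorm(8, mean = i / 4))
  names(groups) <- c("a", "b", "c")
  tk <- tukey_kramer(groups)
  n <- 8
  s2 <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0)) / (24 - 3)
  q_ab <- abs(mean(groups$a) - mean(groups$b)) / sqrt(s2 / n)
  expect_equal(tk$q["a", "b"], q_ab, tolerance = 1e-12)
  # identical groups: all p = 1
  same <- list(a = c(1, 2), b = c(1, 2), c = c(1, 2))
  expect_true(all(tukey_kramer(same)$p == 1))
  expect_error(tukey_kramer(list(a = 1:3)), "two groups")
})

# ---- fabricated scenario results for report-structure tests ------------

fake_result <- function(scenario, ie_offset = 0, peaks) {
  grid <- seq(50, 128, by = 2)
  mk <- function(body) {
    data.frame(flexion = grid, FE = grid, VV = 15 + 0.01 * grid,
               IE = 3 + ie_offset + 0.005 * grid, ML = -0.2, AP = 0.1,
               SI = -0.1, body = body)
  }
  csum <- expand.grid(region = c("trochlea", "capitellum"),
                      step = 1:5, KEEP.OUT.ATTRS = FALSE)
  csum$peak_pressure <- 2; csum$contact_area <- 400
  csum$frac_contact <- 0.5
  csum$flexion <- 50 + csum$step * 15
  structure(list(scenario = scenario, samples_ulna = mk("ulna"),
                 samples_radius = mk("radius"), contact_summary = csum,
                 peak_pressure = 2, ligament_peaks = peaks,
                 dislocation = list(
                   trochlea = list(flag = FALSE, max_lost_span = 0),
                   capitellum = list(flag = FALSE, max_lost_span = 0)),
                 steps = data.frame(step = 1:5, flexion = 50 + (1:5) * 15),
                 grid = c(50, 130, 2)),
            class = "scenario_result")
}

peaks_tbl <- function(...) {
  v <- list(...)
  data.frame(complex = c("LUCL", "MCL_AB", "MCL_PB", "RCL", "annular"),
             active = !vapply(v, is.na, TRUE),
             peak_load = unlist(v),
             max_strain = unlist(v) / 400)
}

fake_results <- function() {
  list(
    intact = fake_result("intact", 0,
                         peaks_tbl(LUCL = 60, MCL_AB = 210, MCL_PB = 120,
                                   RCL = 25, annular = 30)),
    MCL_AB_deficient = fake_result(
      "MCL_AB_deficient", 1.5,
      peaks_tbl(LUCL = 58, MCL_AB = NA, MCL_PB = 140, RCL = 22,
                annular = 28)),
    both_MCL_deficient = fake_result(
      "both_MCL_deficient", 20,
      peaks_tbl(LUCL = 45, MCL_AB = NA, MCL_PB = NA, RCL = 20,
                annular = 25)))
}

test_that("study statistics lay out per-body per-DOF comparisons", {
  res <- fake_results()
  st <- study_statistics(res)
  expect_setequal(unique(st$body), c("ulna", "radius"))
  expect_setequal(unique(st$dof), c("IE", "VV", "SI", "AP", "ML"))
  row <- st[st$body == "ulna" & st$dof == "IE" &
              st$scenario == "both_MCL_deficient", ]
  expect_equal(row$mean_diff, 20)
  expect_equal(row$sd_diff, 0)
  expect_true(row$significant)
  # zero-difference DOFs are not significant
  row0 <- st[st$body == "ulna" & st$dof == "ML" &
               st$scenario == "both_MCL_deficient", ]
  expect_equal(row0$mean_diff, 0)
  expect_error(study_statistics(res["MCL_AB_deficient"]), "intact")
})

test_that("report renders sectioned complexes as missing and is reproducible", {
  res <- fake_results()
  rep <- build_report(res)
  lt <- rep$ligament_table
  # intact column has all four collateral complexes present
  li <- lt[lt$scenario == "intact", ]
  expect_true(all(!is.na(li$peak_load[li$complex %in%
                                        c("LUCL", "RCL", "MCL_AB", "MCL_PB")])))
  # sectioned rows are missing values
  expect_true(is.na(lt$peak_load[lt$scenario == "both_MCL_deficient" &
                                   lt$complex == "MCL_AB"]))
  expect_true(is.na(lt$peak_load[lt$scenario == "MCL_AB_deficient" &
                                   lt$complex == "MCL_AB"]))
  expect_false(is.na(lt$peak_load[lt$scenario == "MCL_AB_deficient" &
                                    lt$complex == "MCL_PB"]))
  # writing twice is byte-identical
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  build_report(res, dir = d1)
  build_report(res, dir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  expect_error(build_report(res["both_MCL_deficient"]), "intact")
})

test_that("dislocation flag needs a sustained full-compartment loss", {
  mk_csum <- function(fracs, flex) {
    data.frame(region = "trochlea", step = seq_along(fracs),
               peak_pressure = 1, contact_area = 100,
               frac_contact = fracs, flexion = flex)
  }
  # short loss (< 10 degrees of flexion): no flag
  f1 <- elbowmbs:::dislocation_flags(
    mk_csum(c(0.5, 0.05, 0.05, 0.5), c(60, 62, 68, 70)))
  expect_false(f1$trochlea$flag)
  # sustained loss over > 10 degrees: flag
  f2 <- elbowmbs:::dislocation_flags(
    mk_csum(c(0.5, 0.05, 0.05, 0.05, 0.5), c(60, 62, 70, 74, 80)))
  expect_true(f2$trochlea$flag)
})
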