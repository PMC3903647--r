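mk_map <- function(cls, sp, sc)
  structure(list(classes = cls, species_id = sp, scenario_id = sc),
            class = "change_class_map")

test_that("incidence maps cells to their class and full-model features", {
  cls <- matrix(c("maintain", "gain", "loss", "unsuitable"), 2, 2)
  cm <- mk_map(cls, "sp1", "A2a")
  fb <- list(sp1 = bin_from(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)))
  inc <- build_incidence(list(cm), fb)
  expect_equal(ncol(inc$incidence), 4)  # G, M, L, Full
  # cell 1 is maintain and full-suitable
  hit <- colnames(inc$incidence)[inc$incidence[1, ]]
  expect_setequal(hit, c("sp1|M|A2a", "sp1|Full|none"))
  # cell 2 is gain only
  expect_setequal(colnames(inc$incidence)[inc$incidence[2, ]], "sp1|G|A2a")
  # cell 4 has no incidences but is retained as a unit
  expect_false(any(inc$incidence[4, ]))
  expect_equal(length(inc$units), 4)
})

test_that("7 species x 2 scenarios yield 49 features on the demo landscape", {
  inc <- demo_incidence()
  expect_equal(ncol(inc$incidence), 7 * 3 * 2 + 7)
  expect_equal(nrow(inc$features), 49)
  # re-running the assembly gives the identical matrix
  cl <- demo_classification()
  inc2 <- build_incidence(cl$class_maps, cl$full_bins)
  expect_identical(inc$incidence, inc2$incidence)
})

test_that("union scenario mode pools scenarios into one feature set", {
  cl <- demo_classification()
  incu <- build_incidence(cl$class_maps, cl$full_bins, scenario_mode = "union")
  expect_equal(ncol(incu$incidence), 7 * 3 + 7)
  inc <- demo_incidence()
  # union incidence is the OR of the per-scenario columns
  g_a <- inc$incidence[, "Mdau|G|A2a"]
  g_b <- inc$incidence[, "Mdau|G|B2a"]
  expect_identical(unname(incu$incidence[, "Mdau|G|union"]),
                   unname(g_a | g_b))
})

test_that("an all-unsuitable landscape produces an all-false incidence", {
  cls <- matrix("unsuitable", 3, 3)
  cm <- mk_map(cls, "sp1", "A2a")
  fb <- list(sp1 = bin_from(matrix(FALSE, 3, 3)))
  inc <- build_incidence(list(cm), fb)
  expect_false(any(inc$incidence))
})

test_that("targets reproduce the published table for the seven study species", {
  statuses <- c(Mdau = "LC", Pkuh = "LC", Hsav = "DD", Nlei = "DD",
                Eser = "LC", Bbar = "DD", Tten = "DD")
  wide <- target_table_wide(statuses)
  expect_equal(nrow(wide), 7)
  cells <- as.matrix(wide[, -(1:2)])
  expect_equal(length(cells), 84)
  for (i in 1:7) {
    base <- if (wide$status[i] == "LC") 3L else 5L
    expect_equal(unname(cells[i, ]), rep(c(base, 2L * base, 4L * base),
                                         each = 4))
  }
  # spot values
  tt1 <- build_targets(statuses, "MN1")
  expect_equal(tt1$target[tt1$species_id == "Bbar" & tt1$kind == "G"], 5L)
  tt3 <- build_targets(statuses, "MN3")
  expect_equal(tt3$target[tt3$species_id == "Mdau" & tt3$kind == "Full"], 12L)
  # per-feature totals: one scenario per class kind -> 3*(4*3) + 4*(4*5)
  expect_equal(sum(tt1$target), 116L)
  # level scaling invariant
  tt2 <- build_targets(statuses, "MN2")
  expect_equal(tt2$target, 2L * tt1$target)
  expect_equal(tt3$target, 4L * tt1$target)
  expect_error(build_targets(c(a = "XX"), "MN1"), "unknown status")
  expect_error(build_targets(character(0), "MN1"), "empty")
})

test_that("coverage report equals brute-force column sums", {
  withr::with_seed(31, {
    m <- matrix(stats::runif(20 * 6) < 0.3, 20, 6)
    inc <- as_feature_incidence(m)
    targets <- sample(0:8, 6, replace = TRUE)
    cov <- coverage_report(inc, targets)
    for (j in 1:6) {
      n_inc <- sum(m[, j])
      expect_equal(cov$n_incident[j], n_inc)
      expect_equal(cov$attainable[j], n_inc >= targets[j])
      expect_equal(cov$max_attainable[j], min(n_inc, targets[j]))
    }
  })
  # hand case: 2 incident units, target 5
  inc2 <- as_feature_incidence(matrix(c(TRUE, TRUE, FALSE), 3, 1))
  cov2 <- coverage_report(inc2, 5L)
  expect_false(cov2$attainable)
  expect_equal(cov2$max_attainable, 2L)
})

test_that("marxan input files are written in the expected dialect", {
  inc <- as_feature_incidence(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  dir <- withr::local_tempdir()
  write_marxan_inputs(inc, c(1L, 2L), dir, locked_in = 2L)
  pu <- utils::read.csv(file.path(dir, "pu.dat"))
  expect_equal(pu$status, c(0L, 2L))
  spec <- utils::read.csv(file.path(dir, "spec.dat"))
  expect_equal(spec$target, c(1L, 2L))
  expect_equal(spec$spf, c(100, 100))
  pv <- utils::read.csv(file.path(dir, "puvspr.dat"))
  expect_equal(nrow(pv), 3)
  expect_true(!is.unsorted(pv$pu))
})
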