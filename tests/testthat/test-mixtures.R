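test_that("mixture_from_ratio distributes the total molarity by ratio", {
  cases <- list(
    list("5:12:3", 1.00, c(KCl = 0.25, "D-Glc" = 0.60, "L-Gln" = 0.15)),
    list("15:12:3", 1.50, c(KCl = 0.75, "D-Glc" = 0.60, "L-Gln" = 0.15)),
    list("0:12:3", 0.75, c("D-Glc" = 0.60, "L-Gln" = 0.15)),
    list("1:0:0", 0.42, c(KCl = 0.42))
  )
  for (cs in cases) {
    m <- mixture_from_ratio(cs[[1]], cs[[2]])
    expect_equal(m$species_molarity[names(cs[[3]])], cs[[3]],
                 tolerance = 1e-12)
    expect_equal(m$total_molarity, cs[[2]], tolerance = 1e-12)
    expect_setequal(names(m$species_molarity), names(cs[[3]]))
  }
})

test_that("ratio parsing rejects malformed input", {
  expect_error(mixture_from_ratio("0:0:0", 1), "all-zero")
  expect_error(mixture_from_ratio("5:-1:3", 1), "non-negative")
  expect_error(mixture_from_ratio("5:12", 1), "entries")
  expect_error(mixture_from_ratio("a:b:c", 1), "unparseable")
  expect_error(mixture_from_ratio("5:12:3", 0), "total_molarity")
  expect_error(mixture(c(0.1, 0.2)), "named")
})

test_that("ratio strings round-trip through mixture_from_ratio", {
  # the recovered string is the smallest-integer normalization, so it is
  # equivalent to (not necessarily identical with) the input
  for (rs in c("5:12:3", "15:12:3", "0:12:3", "5:12:0", "15:22:3")) {
    m <- mixture_from_ratio(rs, 1.23)
    back <- mixture_from_ratio(mixture_ratio_string(m), 1.23)
    expect_equal(back$species_molarity, m$species_molarity,
                 tolerance = 1e-9, label = rs)
  }
  # already-reduced strings come back verbatim
  expect_identical(
    mixture_ratio_string(mixture_from_ratio("5:12:3", 1)), "5:12:3")
  expect_identical(
    mixture_ratio_string(mixture_from_ratio("15:12:3", 1.5)), "5:4:1")
})

test_that("gamma factors follow the per-species policy", {
  expect_identical(gamma_factor("D-Glc"), 1)
  expect_equal(gamma_factor("KCl"), 0.90 * 2)
  # oracle: back-calculate the glutamine factor from the two-component
  # rows (estimated potentials 2.23 and 2.62 MPa; Glc 0.60 M, Gln 0.15 M)
  p <- osmotic_model_params()
  gamma_gln_oracle <- (2.23e6 / (p$R * p$T) / 1000 - 0.60) / 0.15
  expect_equal(round(gamma_gln_oracle, 2), 1.96)
  expect_equal(gamma_factor("L-Gln"), 1.96)
  # custom-constant and invalid modes
  sp <- osmolyte_species("X", gamma_mode = "constant", gamma_constant = 1.3)
  expect_equal(gamma_factor(sp), 1.3)
  expect_error(osmolyte_species("X", gamma_mode = "constant"), "finite")
  expect_error(gamma_factor("unobtainium"), "unknown species")
})

test_that("estimated potentials reproduce the printed reference rows", {
  mixes <- table1_mixtures()
  # the 1.5 M three-component rows are excluded: their printed cells are
  # inconsistent with the concentration-independent gamma set
  for (nm in c("KCl", "M1", "M1a", "M1b")) {
    est <- estimate_osmotic_potential(mixes[[nm]])
    expect_equal(round(est, 2),
                 printed_table$estimated[printed_table$name == nm],
                 tolerance = 1e-12, label = nm)
  }
  expect_equal(estimate_osmotic_potential(mixture(numeric(0))), 0)
})

test_that("estimator is additive over species and linear in molarity", {
  p <- osmotic_model_params()
  set.seed(41)
  for (i in 1:20) {
    m <- runif(3, 0, 1.2)
    full <- mixture(c(KCl = m[1], "D-Glc" = m[2], "L-Gln" = m[3]))
    parts <- sum(vapply(c(KCl = 1, "D-Glc" = 2, "L-Gln" = 3), function(j) {
      v <- setNames(m[j], c("KCl", "D-Glc", "L-Gln")[j])
      estimate_osmotic_potential(mixture(v), p)
    }, numeric(1)))
    expect_equal(estimate_osmotic_potential(full, p), parts,
                 tolerance = 1e-12)
    lam <- runif(1, 0.1, 5)
    scaled <- mixture(setNames(lam * m, c("KCl", "D-Glc", "L-Gln")))
    expect_equal(estimate_osmotic_potential(scaled, p),
                 lam * estimate_osmotic_potential(full, p),
                 tolerance = 1e-12)
  }
})

test_that("osmotic potential ratio and its display rounding", {
  expect_equal(osmotic_potential_ratio(2.93, 3.35, digits = 2), 0.87)
  expect_equal(osmotic_potential_ratio(4.83, 5.11, digits = 2), 0.95)
  expect_equal(osmotic_potential_ratio(1.7, 1.7), 1)
  expect_error(osmotic_potential_ratio(1, 0), "> 0")
  expect_error(osmotic_potential_ratio(-1, 2), ">= 0")
})

test_that("association degree reconstructs the printed degrees", {
  expect_equal(association_degree(0.87), 19.5)
  expect_equal(association_degree(0.88), 18.0)
  expect_equal(association_degree(0.85), 22.5)
  expect_equal(association_degree(0.95), 7.5)
  expect_equal(association_degree(1.00), 0)
  expect_equal(association_degree(1.01), 0)  # no negative degrees
  expect_error(association_degree(0), "> 0")
  # non-increasing in the ratio
  r <- seq(0.5, 1.2, by = 0.01)
  expect_true(all(diff(association_degree(r)) <= 0))
})

test_that("anomer fractions normalize intensities to percentages", {
  expect_equal(anomer_fractions(36, 64), c(alpha = 36, beta = 64))
  expect_equal(anomer_fractions(77, 23), c(alpha = 77, beta = 23))
  expect_equal(anomer_fractions(5, 5), c(alpha = 50, beta = 50))
  expect_equal(sum(anomer_fractions(0.123, 7.7)), 100)
  expect_error(anomer_fractions(0, 0), "both")
  expect_error(anomer_fractions(-1, 2), ">= 0")
})

test_that("table1_report composes the constituent operations", {
  mixes <- table1_mixtures()
  meas <- table1_measured()
  measured <- setNames(meas$measured_MPa, meas$name)
  tab <- table1_report(mixes, measured)
  expect_identical(tab$name, names(mixes))
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    est <- estimate_osmotic_potential(mixes[[nm]])
    expect_equal(tab$estimated_MPa[i], est, tolerance = 1e-12)
    expect_equal(tab$ratio[i], measured[[nm]] / est, tolerance = 1e-12)
    if (length(mixes[[nm]]$species_molarity) == 3) {
      expect_equal(tab$assoc_degree_pct[i],
                   association_degree(measured[[nm]] / est))
    } else {
      expect_true(is.na(tab$assoc_degree_pct[i]))
    }
  }
  # degree column blank for a single ideal species at measured = estimated
  solo <- list(G = mixture(c("D-Glc" = 0.5), name = "G"))
  est <- estimate_osmotic_potential(solo$G)
  t1 <- table1_report(solo, c(G = est))
  expect_equal(t1$ratio, 1)
  expect_true(is.na(t1$assoc_degree_pct))
  expect_error(table1_report(list(), c()), "empty")
})
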