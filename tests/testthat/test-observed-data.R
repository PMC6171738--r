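printed_percentages <- list(
  c("TK", "GABA", 84.6), c("FMRF", "GABA", 92.8), c("Mas-AT", "GABA", 97.2),
  c("MIP", "GABA", 97.5), c("AST-A", "GABA", 96.7),
  c("TK", "MIP", 100), c("TK", "FMRF", 0), c("TK", "Mas-AT", 0),
  c("MIP", "Mas-AT", 42), c("Mas-AT", "FMRF", 22))

test_that("packaged panel round-trips losslessly through CSV", {
  panel <- observed_panel()
  expect_equal(panel$count_mean,
               c(12.16, 58.16, 143.58, 150.66, 47.4, 170))
  expect_equal(panel$count_sd, c(0.55, 17.48, 24.38, 16.79, 12.83, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(panel, path)
  back <- read_panel_csv(path)
  expect_equal(back$transmitter, panel$transmitter)
  expect_equal(back$count_mean, panel$count_mean)
  expect_equal(back$count_sd, panel$count_sd)
  expect_true("provenance" %in% names(back))  # unknown columns preserved
})

test_that("ratio CSV parsing validates and handles CRLF", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("source,target,percent\nA,B,101", path)
  expect_error(read_ratio_csv(path), "outside \\[0, 100\\].*row 1")
  writeLines("source,target,percent\r\nA,B,42.5\r\nB,C,0\r\n", path,
             sep = "")
  crlf <- read_ratio_csv(path)
  expect_equal(crlf$percent, c(42.5, 0))
  out <- withr::local_tempfile(fileext = ".csv")
  write_ratio_csv(crlf, out)
  expect_equal(read_ratio_csv(out), crlf)
})

test_that("reverse ratios follow the overlap identity", {
  expect_equal(derive_reverse_ratio(1.00, 12.16, 150.66), 0.0807,
               tolerance = 1e-3)
  expect_equal(derive_reverse_ratio(0.42, 150.66, 143.58), 0.4407,
               tolerance = 1e-3)
  expect_equal(derive_reverse_ratio(0, 99, 7), 0)
  expect_equal(derive_reverse_ratio(0.9, 200, 50), 1)  # clipped
  expect_error(derive_reverse_ratio(0.5, 10, 0), "> 0")
  tab <- observed_ratios(derived = TRUE)
  cnt <- stats::setNames(observed_panel()$count_mean,
                         observed_panel()$transmitter)
  fwd <- tab[!tab$derived, ]
  rev <- tab[tab$derived, ]
  # ratio(X->Y) * n_X == ratio(Y->X) * n_Y up to the [0,1] clip
  expect_equal(pmin(fwd$percent * cnt[fwd$source] / 100,
                    cnt[fwd$target]),
               rev$percent * cnt[rev$source] / 100,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("reconstructed fixture reproduces every printed percentage", {
  fx <- reconstruct_fixture()
  r <- coexpression_ratios(fx$matrix)
  for (pp in printed_percentages) {
    got <- floor(1000 * r$ratio[pp[1], pp[2]] + 0.5) / 10  # half-up, 1 dp
    expect_equal(got, as.numeric(pp[3]),
                 label = paste(pp[1], "->", pp[2]))
  }
})

test_that("fixture counts stay inside the replicate-scaled windows", {
  fx <- reconstruct_fixture()
  panel <- observed_panel()
  reps <- fx$replicates
  for (t in c("TK", "FMRF", "Mas-AT", "MIP", "AST-A")) {
    i <- match(t, panel$transmitter)
    lo <- reps * (panel$count_mean[i] - panel$count_sd[i])
    hi <- reps * (panel$count_mean[i] + panel$count_sd[i])
    expect_gte(fx$counts[[t]], floor(lo))
    expect_lte(fx$counts[[t]], ceiling(hi))
  }
  # the GABA column is constraint-driven (union of required overlaps) and
  # its realized size is reported in the manifest
  expect_equal(unname(fx$counts[["GABA"]]), sum(fx$matrix[, "GABA"]))
  expect_match(fx$manifest$gaba_count_note, "union")
})

test_that("fixture overlaps satisfy exact integer identities", {
  fx <- reconstruct_fixture()
  r <- coexpression_ratios(fx$matrix)
  expect_identical(r$overlap, t(r$overlap))
  cnt <- r$counts
  for (s in rownames(r$ratio)) for (t in colnames(r$ratio))
    expect_equal(r$ratio[s, t] * cnt[s], r$overlap[s, t] + 0,
                 ignore_attr = TRUE)
  # TK is fully nested in MIP and disjoint from FMRF and Mas-AT
  expect_equal(unname(r$overlap["TK", "MIP"]), unname(cnt[["TK"]]))
  expect_equal(unname(r$overlap["TK", "FMRF"]), 0)
  expect_equal(unname(r$overlap["TK", "Mas-AT"]), 0)
})

test_that("fixture construction is deterministic and RNG-free", {
  set.seed(99)
  seed_state <- .Random.seed
  f1 <- reconstruct_fixture()
  expect_identical(.Random.seed, seed_state)  # no RNG consumed
  f2 <- reconstruct_fixture()
  expect_identical(f1$matrix, f2$matrix)
  expect_identical(f1$manifest, f2$manifest)
})

test_that("fixture_observed merges fixture means with external SDs", {
  fx <- reconstruct_fixture()
  sds <- data.frame(source = c("MIP", "Mas-AT"),
                    target = c("Mas-AT", "FMRF"),
                    sd = c(0.03, 0.04))
  obs <- fixture_observed(fx, sds)
  row <- obs[obs$source == "MIP" & obs$target == "Mas-AT", ]
  expect_equal(row$mean, 0.42, tolerance = 1e-3)
  expect_equal(row$sd, 0.03)
  # overlap rescaled to per-AL counts
  expect_equal(row$overlap,
               coexpression_ratios(fx$matrix)$overlap["MIP", "Mas-AT"] /
                 fx$replicates)
  expect_true(all(is.na(obs$sd[!(paste(obs$source, obs$target) %in%
                                   paste(sds$source, sds$target))])))
})
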