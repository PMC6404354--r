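test_that("aac computes compositions over non-X symbols", {
  w <- rep("A", 15)
  v <- aac(w)
  expect_equal(unname(v["AAC.A"]), 1)
  expect_equal(sum(v), 1)
  expect_length(v, 20)

  w <- c(rep("X", 7), "N", "V", "S", "A", rep("X", 4))
  v <- aac(w)
  expect_equal(unname(v[c("AAC.N", "AAC.V", "AAC.S", "AAC.A")]),
               rep(0.25, 4))
  expect_warning(v0 <- aac(rep("X", 15)), "no standard residues")
  expect_equal(sum(v0), 0)
})

test_that("dpc computes ordered dipeptide frequencies", {
  expect_equal(unname(dpc(rep("A", 15))["DPC.AA"]), 1)
  w <- strsplit("ACACACACACACACA", "")[[1]]
  v <- dpc(w)
  expect_equal(unname(v["DPC.AC"]), 0.5)
  expect_equal(unname(v["DPC.CA"]), 0.5)
  expect_length(v, 400)
  expect_warning(dpc(c("A", rep("X", 14))), "fewer than 2")
})

test_that("aac and dpc sum to one on X-free random windows", {
  set.seed(11)
  for (i in 1:20) {
    w <- random_window(with_x = FALSE)
    expect_equal(sum(aac(w)), 1, tolerance = 1e-12)
    expect_equal(sum(dpc(w)), 1, tolerance = 1e-12)
  }
})

test_that("autocorrelation matches closed forms and dimensions", {
  props <- default_autocorr_properties()
  # constant window: normalized Moreau-Broto AC(d) = P^2 for feasible lags
  w <- rep("A", 15)
  v <- autocorrelation(w, "moreau-broto", props[1], nlag = 30)
  pA <- unname(props[[1]]["A"])
  expect_equal(unname(v[1:14]), rep(pA^2, 14), tolerance = 1e-12)
  expect_equal(unname(v[15:30]), rep(0, 16))

  expect_length(autocorrelation(random_window(), "moreau-broto",
                                props, 30), 240)
  # constant property over window degenerates Moran/Geary to 0
  expect_warning(vm <- autocorrelation(w, "moran", props[1], 5), "constant")
  expect_equal(unname(vm), rep(0, 5))
})

test_that("ctd composition/transition behave on single-class windows and
           total 147 features", {
  # all residues in hydrophobicity class 1 (polar)
  w <- rep(c("R", "K", "E"), 5)
  v <- ctd(w)
  expect_equal(unname(v[c("CTD.hydrophobicity.C1", "CTD.hydrophobicity.C2",
                          "CTD.hydrophobicity.C3")]), c(1, 0, 0))
  expect_equal(unname(v[startsWith(names(v), "CTD.hydrophobicity.T")]),
               rep(0, 3))
  expect_length(v, 147)
})

test_that("sequence_order zeroes out on identical residues and has the
           documented dimensions", {
  v <- sequence_order(rep("A", 15))
  socn <- v[startsWith(names(v), "SOCN.")]
  qso_ord <- v[grepl("^QSO\\..*\\.d[0-9]+$", names(v))]
  expect_equal(unname(socn), rep(0, 60))
  expect_equal(unname(qso_ord), rep(0, 60))
  expect_length(socn, 60)
  expect_length(v[startsWith(names(v), "QSO.")], 100)
})

test_that("pseaac reduces to AAC at w = 0 and has length 50", {
  w <- random_window()
  for (type in 1:2) {
    v <- pseaac(w, type, w = 0)
    expect_length(v, 50)
    expect_equal(unname(v[1:20]), unname(aac(w)), tolerance = 1e-12)
  }
})

test_that("aaindex_encode produces positional property values", {
  tabs <- default_aaindex_tables()
  expect_length(aaindex_encode(random_window(), tabs), 15 * length(tabs))
  expect_equal(unname(aaindex_encode(rep("X", 15), tabs)),
               rep(0, 15 * length(tabs)))
  # single index checkable by hand: indicator on A, z-scored
  pt <- property_table("ind", setNames(c(1, rep(0, 19)),
                                       c("A", setdiff(glycopu:::AA20, "A"))))
  w <- c("A", "C", "A", rep("G", 12))
  v <- aaindex_encode(w, list(IND = pt))
  expect_equal(unname(v[1]), unname(pt["A"]))
  expect_equal(unname(v[2]), unname(pt["C"]))
  expect_equal(unname(v[4]), unname(pt["G"]))
})

test_that("read_aaindex parses the vendored snapshot and drops NA entries", {
  tabs <- read_aaindex(system.file("extdata", "aaindex1_subset.txt",
                                   package = "glycopu"))
  expect_length(tabs, 10)
  expect_true("KYTJ820101" %in% names(tabs))
  # z-scored: mean 0, sd 1 over the 20 residues
  kd <- tabs$KYTJ820101[glycopu:::AA20]
  expect_equal(mean(kd), 0, tolerance = 1e-9)
  expect_equal(sd(kd), 1, tolerance = 1e-9)
  expect_equal(unname(tabs$KYTJ820101["X"]), 0)

  broken <- tempfile()
  writeLines(c("H BROKEN0001", "D has a missing value",
               "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
               paste(c("NA", rep("1.0", 9)), collapse = "   "),
               paste(rep("1.0", 10), collapse = "   "), "//"), broken)
  expect_warning(tabs2 <- read_aaindex(broken), "missing values")
  expect_length(tabs2, 0)
})

test_that("property_table validates coverage and z-scores correctly", {
  expect_error(property_table("bad", c(A = 1)), "must cover")
  pt <- property_table("raw", setNames(1:20, glycopu:::AA20),
                       normalization = "none")
  expect_equal(unname(pt["X"]), mean(1:20))
})

test_that("extract_all concatenates enabled groups deterministically", {
  w <- random_window()
  cfg <- descriptor_config(groups = "AAC")
  expect_length(extract_all(w, cfg), 20)

  full <- extract_all(w)
  expect_length(full, 20 + 400 + 720 + 147 + 160 + 100 + 15 * 10)
  expect_identical(full, extract_all(w))
  expect_false(any(duplicated(names(full))))

  # descriptors depend only on the window symbols, not protein identity
  prot <- c(a = paste(c(w, w), collapse = ""),
            b = paste(c(rep("G", 5), w), collapse = ""))
  f1 <- extract_all(extract_window(prot[["a"]], 8))
  f2 <- extract_all(extract_window(prot[["b"]], 13))
  expect_identical(f1, f2)
})

test_that("extract_features builds keyed matrices", {
  proteins <- c(a = "NVSANVSAGGGGGGG", b = "WWTTSSNNNNVSAGG")
  sites <- data.frame(protein_id = c("a", "b"), position = c(1L, 10L))
  m <- extract_features(proteins, sites,
                        descriptor_config(groups = c("AAC", "CTD")))
  expect_equal(dim(m), c(2L, 167L))
  expect_equal(rownames(m), c("a:1", "b:10"))
})
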