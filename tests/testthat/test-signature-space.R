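test_that("cosine similarity matches hand-computed values", {
  a <- c(1, 1, rep(0, 94)); b <- c(1, rep(0, 95))
  expect_equal(cosineSimilarity(a, b), 1 / sqrt(2), tolerance = 1e-12)
  x <- c(3, 1, 4, rep(0, 93))
  expect_equal(cosineSimilarity(x, x), 1)
  expect_equal(cosineSimilarity(c(1, 0, rep(0, 94)), c(0, 1, rep(0, 94))), 0)
  expect_error(cosineSimilarity(rep(0, 96), x), "zero vector")
  expect_error(cosineSimilarity(c(-1, x[-1]), x), "nonnegative")
})

test_that("cosine similarity is symmetric, scale-invariant and bounded", {
  set.seed(1)
  for (i in 1:25) {
    a <- stats::rgamma(96, 0.5); b <- stats::rgamma(96, 0.5)
    cs <- cosineSimilarity(a, b)
    expect_gte(cs, 0); expect_lte(cs, 1)
    expect_equal(cs, cosineSimilarity(b, a), tolerance = 1e-14)
    expect_equal(cs, cosineSimilarity(a * 1000, b / 17), tolerance = 1e-12)
  }
})

test_that("CS matrix equals element-wise brute-force recomputation", {
  sigs <- makeSyntheticSignatures(nSignatures = 5, seed = 2)
  set.seed(3)
  sp <- matrix(rpois(10 * 96, 20), 10, 96,
               dimnames = list(paste0("s", 1:10), sbsChannels()))
  cs <- buildCSMatrix(sp, sigs)
  v <- csValues(cs)
  for (i in 1:10) for (j in 1:5) {
    a <- sp[i, ]; b <- signatureMatrix(sigs)[, j]
    expect_equal(v[i, j], sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
                 tolerance = 1e-12)
  }
})

test_that("spectra equal to scaled signature columns give a unit diagonal", {
  sigs <- makeSyntheticSignatures(nSignatures = 4, seed = 5)
  sp <- t(signatureMatrix(sigs)) * 1000
  rownames(sp) <- paste0("s", 1:4)
  v <- csValues(buildCSMatrix(sp, sigs))
  expect_equal(unname(diag(v)), rep(1, 4), tolerance = 1e-12)
})

test_that("zero-count samples are flagged undefined, not silently zero", {
  sigs <- makeSyntheticSignatures(nSignatures = 3, seed = 1)
  sp <- matrix(c(rep(1, 96), rep(0, 96)), 2, 96, byrow = TRUE,
               dimnames = list(c("ok", "empty"), sbsChannels()))
  expect_warning(cs <- buildCSMatrix(sp, sigs), "undefined")
  expect_identical(undefinedSamples(cs), "empty")
  expect_true(all(is.na(csValues(cs)["empty", ])))
  expect_false(anyNA(csValues(cs)["ok", ]))
})

test_that("label mismatch raises an alignment error naming the offender", {
  sigs <- makeSyntheticSignatures(nSignatures = 3, seed = 1)
  sp <- matrix(1, 2, 96, dimnames = list(c("a", "b"),
                                         c("BOGUS", sbsChannels()[-1])))
  expect_error(buildCSMatrix(sp, sigs), "BOGUS")
})

test_that("the signature reader matches channels by label, not position", {
  sigs <- makeSyntheticSignatures(nSignatures = 4, seed = 9)
  p <- tempfile(fileext = ".tsv")
  df <- data.frame(Type = channelLabels(sigs), signatureMatrix(sigs),
                   check.names = FALSE)
  df <- df[sample(nrow(df)), ]  # shuffle the rows
  data.table::fwrite(df, p, sep = "\t")
  back <- readSignatureSet(p)
  expect_equal(signatureMatrix(back), signatureMatrix(sigs),
               tolerance = 1e-12)
})

test_that("unnormalized signature columns are renormalized with a warning", {
  sigs <- makeSyntheticSignatures(nSignatures = 3, seed = 4)
  m <- signatureMatrix(sigs) * 3
  expect_warning(out <- SignatureSet(m), "renormalizing")
  expect_equal(colSums(signatureMatrix(out)), colSums(signatureMatrix(sigs)),
               tolerance = 1e-9)
})

test_that("filter boundary semantics: >= at both thresholds retains", {
  # 10 samples x 2 signatures: A reaches 0.24 in exactly 1 sample
  # (prevalence 0.10, retained); B in none (dropped).
  v <- matrix(0.1, 10, 2, dimnames = list(paste0("s", 1:10), c("A", "B")))
  v[1, "A"] <- 0.24
  cs <- new("CSMatrix", values = v, undefined = rep(FALSE, 10))
  ret <- filterSignatures(cs, csThreshold = 0.24, minPrevalence = 0.10)
  expect_identical(retainedNames(ret), "A")
  expect_equal(ret@prevalence, c(0.1, 0))
})

test_that("a vacuous prevalence threshold retains everything", {
  co <- fixtureCohort(n = 20, seed = 2)
  cs <- buildCSMatrix(co$spectra, fixtureSignatures())
  ret <- filterSignatures(cs, csThreshold = 0.24, minPrevalence = 0)
  expect_identical(retainedNames(ret), signatureNames(fixtureSignatures()))
})

test_that("filtering is monotone in both thresholds", {
  set.seed(8)
  v <- matrix(runif(30 * 8), 30, 8,
              dimnames = list(paste0("s", 1:30), paste0("SIG", 1:8)))
  cs <- new("CSMatrix", values = v, undefined = rep(FALSE, 30))
  nRetained <- function(th, pr) {
    r <- tryCatch(filterSignatures(cs, th, pr),
                  error = function(e) NULL)
    if (is.null(r)) 0L else sum(r@retained)
  }
  for (pr in c(0.05, 0.2, 0.5)) {
    counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), nRetained, integer(1), pr = pr)
    expect_true(all(diff(counts) <= 0))
  }
  for (th in c(0.2, 0.5)) {
    counts <- vapply(c(0.05, 0.2, 0.5, 0.8), function(p) nRetained(th, p),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("filtering everything out is a hard, instructive error", {
  v <- matrix(0.01, 5, 2, dimnames = list(paste0("s", 1:5), c("A", "B")))
  cs <- new("CSMatrix", values = v, undefined = rep(FALSE, 5))
  expect_error(filterSignatures(cs), "csThreshold")
})

test_that("undefined samples are excluded from prevalence denominators", {
  v <- rbind(matrix(0.5, 4, 2), matrix(NA_real_, 6, 2))
  dimnames(v) <- list(paste0("s", 1:10), c("A", "B"))
  cs <- new("CSMatrix", values = v, undefined = c(rep(FALSE, 4), rep(TRUE, 6)))
  ret <- filterSignatures(cs, 0.24, 0.10)
  expect_equal(ret@prevalence, c(1, 1))  # 4/4, not 4/10
})
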