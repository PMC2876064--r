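test_that("annotation reading applies exclusions and drops emptied pathways", {
  d <- withr::local_tempdir()
  fx <- write_annotation_fixture(
    d,
    rows = c("t1\tP1\tm1", "t1\tP1\tm2", "t1\tP2\tm2"),
    taxa = c("taxon_id\torf_count\tmotility", "t1\t1000\tmotile"))

  ann <- read_annotations(fx$annotations, fx$taxa, exclusions = character())
  expect_equal(ann$taxa$t1, list(P1 = c("m1", "m2"), P2 = "m2"))
  expect_equal(ann$metadata$motility, "motile")

  expect_message(
    ann2 <- read_annotations(fx$annotations, fx$taxa, exclusions = "m2"),
    "dropped")
  expect_equal(ann2$taxa$t1, list(P1 = "m1"))

  # empty annotations file is fine
  writeLines("taxon_id\tpathway_id\tmetabolite_id", fx$annotations)
  ann3 <- read_annotations(fx$annotations, fx$taxa)
  expect_equal(n_taxa(ann3), 0L)
})

test_that("malformed rows and missing metadata are reported with context", {
  d <- withr::local_tempdir()
  fx <- write_annotation_fixture(
    d,
    rows = c("t1\tP1\tm1", "t1\tP1"),
    taxa = c("taxon_id\torf_count", "t1\t100"))
  expect_error(read_annotations(fx$annotations, fx$taxa), "line 3")

  fx <- write_annotation_fixture(
    d,
    rows = c("t1\tP1\tm1", "t2\tP1\tm1"),
    taxa = c("taxon_id\torf_count", "t1\t100"))
  expect_error(read_annotations(fx$annotations, fx$taxa), "t2")
})

test_that("write/read round-trips canonical annotation TSVs byte-identically", {
  ann <- annotation_set(
    list(tB = list(P2 = c("m3", "m1"), P1 = "m2"),
         tA = list(P1 = c("m2", "m1"))),
    data.frame(taxon_id = c("tA", "tB"), orf_count = c(10L, 20L),
               habitat = c("soil", NA), stringsAsFactors = FALSE))
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.tsv"); p2 <- file.path(d, "t.tsv")
  write_annotations(ann, p1, p2)
  back <- read_annotations(p1, p2, exclusions = character())
  expect_equal(back$taxa, ann$taxa)
  expect_equal(back$metadata, ann$metadata)
  p3 <- file.path(d, "a2.tsv"); p4 <- file.path(d, "t2.tsv")
  write_annotations(back, p3, p4)
  expect_identical(readLines(p1), readLines(p3))
  expect_identical(readLines(p2), readLines(p4))
})

test_that("consistency filter removes the planted under-annotated taxon", {
  # n_pathways = 10*log(orf) + noise for 20 taxa; one deflated by 50%
  set.seed(11)
  orf <- round(stats::runif(21, 500, 9000))
  npath <- round(10 * log(orf) + stats::rnorm(21, 0, 1.5))
  npath[21] <- round(npath[21] * 0.5)
  taxa <- list(); meta <- list()
  mets <- sprintf("m%04d", 1:4000)
  for (i in 1:21) {
    tx <- sprintf("t%02d", i)
    taxa[[tx]] <- stats::setNames(
      lapply(seq_len(npath[i]), function(j) mets[j]),
      sprintf("P%03d", seq_len(npath[i])))
    meta[[i]] <- data.frame(taxon_id = tx, orf_count = orf[i])
  }
  ann <- annotation_set(taxa, do.call(rbind, meta))
  out <- filter_consistent_taxa(ann, quantile = 0.05)
  expect_equal(out$filter$removed, "t21")
  expect_equal(n_taxa(out$annotations), 20L)

  # independent least-squares oracle via normal equations
  X <- cbind(1, log(orf))
  beta <- solve(crossprod(X), crossprod(X, npath))
  expect_equal(out$filter$intercept, beta[1], tolerance = 1e-10)
  expect_equal(out$filter$slope, beta[2], tolerance = 1e-10)
  res <- npath - X %*% beta
  expect_equal(unname(out$filter$residuals), as.numeric(res), tolerance = 1e-8)

  # quantile 0 removes nobody and keeps the set unchanged
  out0 <- filter_consistent_taxa(ann, quantile = 0)
  expect_equal(out0$filter$removed, character())
  expect_equal(out0$annotations$taxa, ann$taxa)

  # exact collinearity gives r^2 = 1
  npath2 <- pmax(1, round(5 * log(orf)))
  taxa2 <- lapply(npath2, function(k) {
    stats::setNames(lapply(seq_len(k), function(j) mets[j]),
                    sprintf("P%03d", seq_len(k)))
  })
  names(taxa2) <- names(taxa)
  orf2 <- round(exp(npath2 / 5))     # make the relation exact
  npath2 <- round(5 * log(orf2))
  ann2 <- annotation_set(taxa2, data.frame(taxon_id = names(taxa2),
                                           orf_count = orf2))
  # rebuild pathway lists to match exact npath2
  expect_gte(filter_consistent_taxa(ann2)$filter$r_squared, 0.99)

  expect_error(filter_consistent_taxa(ann, quantile = 1.2), "quantile")
  ann3 <- annotation_set(taxa, data.frame(taxon_id = names(taxa),
                                          orf_count = rep(100L, 21)))
  expect_error(filter_consistent_taxa(ann3), "degenerate")
})

test_that("strain merging unions annotations and validates labels", {
  ann <- annotation_set(
    list(s1 = list(P1 = "m1"),
         s2 = list(P1 = "m2", P2 = "m3"),
         s3 = list(P3 = "m4")),
    data.frame(taxon_id = c("s1", "s2", "s3"), orf_count = c(5L, 9L, 2L),
               motility = c("motile", NA, "immotile"),
               stringsAsFactors = FALSE))
  merged <- merge_strains(ann, c(s1 = "sp", s2 = "sp"))
  expect_equal(merged$taxa$sp, list(P1 = c("m1", "m2"), P2 = "m3"))
  expect_equal(merged$metadata$orf_count[merged$metadata$taxon_id == "sp"], 9L)
  expect_equal(merged$metadata$motility[merged$metadata$taxon_id == "sp"],
               "motile")

  # identity map leaves the set unchanged; merging is idempotent
  idmap <- stats::setNames(names(merged$taxa), names(merged$taxa))
  again <- merge_strains(merged, idmap)
  expect_equal(again$taxa, merged$taxa)
  expect_equal(again$metadata, merged$metadata)

  ann2 <- annotation_set(
    list(s1 = list(P1 = "m1"), s2 = list(P1 = "m2")),
    data.frame(taxon_id = c("s1", "s2"), orf_count = c(1L, 1L),
               motility = c("motile", "immotile"), stringsAsFactors = FALSE))
  expect_error(merge_strains(ann2, c(s1 = "sp", s2 = "sp")),
               "conflicting 'motility'")
})
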