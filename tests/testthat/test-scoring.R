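## Hand-rolled count table: one tile, one replicate.
manual_counts <- function(pre, post) {
  data.frame(
    variant_id = rep(names(pre), 2),
    construct = "FL", condition = "cSrc_KD", tile = 1L, replicate = 1L,
    timepoint = rep(c("pre", "post"), each = length(pre)),
    count = c(unname(pre), unname(post)),
    stringsAsFactors = FALSE
  )
}

test_that("enrichment scores follow the WT-normalized log2 ratio", {
  counts <- manual_counts(c(WT = 1000, A1C = 100, A2C = 50),
                          c(WT = 1000, A1C = 400, A2C = 50))
  rs <- enrichment_scores(counts, pseudocount = 0)
  expect_equal(rs$score[rs$variant_id == "A1C"], 2.0)  # hand-computed
  ## counts proportional to WT in pre and post score exactly 0
  counts2 <- manual_counts(c(WT = 1000, A1C = 100), c(WT = 2000, A1C = 200))
  rs2 <- enrichment_scores(counts2, pseudocount = 0)
  expect_equal(rs2$score[rs2$variant_id == "A1C"], 0)
  ## pseudocount guards division by zero
  counts3 <- manual_counts(c(WT = 1000, A1C = 0), c(WT = 1000, A1C = 10))
  rs3 <- enrichment_scores(counts3, pseudocount = 0.5)
  expect_true(is.finite(rs3$score[rs3$variant_id == "A1C"]))
  ## low-coverage variants get flagged
  rs4 <- enrichment_scores(manual_counts(c(WT = 1000, A1C = 5),
                                         c(WT = 1000, A1C = 5)),
                           min_reads = 10)
  expect_true(rs4$flagged[rs4$variant_id == "A1C"])
  ## a tile without WT cannot be normalized
  noWT <- manual_counts(c(A1C = 10, A2C = 10), c(A1C = 10, A2C = 10))
  expect_error(enrichment_scores(noWT), "WT row absent")
})

test_that("WT scores are exactly zero in every tile and replicate", {
  s <- small_sim(length = 24, depth = 4000)
  rs <- enrichment_scores(s$sim$counts)
  wt <- rs[rs$variant_id == "WT", ]
  expect_equal(nrow(wt), nrow(s$sim$tiles) * s$cfg$n_replicates)
  expect_true(all(wt$score == 0))
})

test_that("scores are scale-equivariant in tile depth", {
  pre <- c(WT = 1200, A1C = 150, A2C = 480)
  post <- c(WT = 900, A1C = 600, A2C = 120)
  base <- enrichment_scores(manual_counts(pre, post), pseudocount = 0)
  scaled <- enrichment_scores(manual_counts(7 * pre, 7 * post),
                              pseudocount = 0)
  expect_equal(base$score, scaled$score)  # exact with p = 0 (up to fp round)
  ## with a pseudocount the invariance is approximate at high counts
  base_p <- enrichment_scores(manual_counts(pre, post), pseudocount = 0.5)
  scaled_p <- enrichment_scores(manual_counts(7 * pre, 7 * post),
                                pseudocount = 0.5)
  expect_equal(base_p$score, scaled_p$score, tolerance = 0.05)
})

test_that("replicate QC retains concordant replicates, drops noise", {
  mk_reps <- function(scores_by_rep) {
    do.call(rbind, lapply(seq_along(scores_by_rep), function(r) {
      data.frame(variant_id = names(scores_by_rep[[r]]),
                 replicate = r, score = unname(scores_by_rep[[r]]),
                 flagged = FALSE, stringsAsFactors = FALSE)
    }))
  }
  set.seed(10)
  truth <- rnorm(200)
  names(truth) <- paste0("A", seq_along(truth), "C")
  good1 <- truth + rnorm(200, sd = 0.1)
  good2 <- truth + rnorm(200, sd = 0.1)
  noise <- rnorm(200)
  names(good1) <- names(good2) <- names(noise) <- names(truth)

  qc <- replicate_qc(mk_reps(list(good1, good2, noise)))
  expect_equal(qc$retained, c(1L, 2L))
  expect_equal(qc$dropped, 3L)
  expect_equal(dim(qc$cor_matrix), c(3L, 3L))

  ## identical replicates: r = 1 everywhere, all retained
  qc2 <- replicate_qc(mk_reps(list(truth, truth, truth)))
  expect_equal(qc2$retained, 1:3)
  expect_true(all(abs(qc2$cor_matrix - 1) < 1e-12))

  ## two replicates: both retained or a hard error, never silent dropping
  expect_equal(replicate_qc(mk_reps(list(good1, good2)))$retained, 1:2)
  expect_error(replicate_qc(mk_reps(list(truth, noise))), "discordant")
  n2 <- rnorm(200)
  n3 <- rnorm(200)
  names(n2) <- names(n3) <- names(truth)
  expect_error(replicate_qc(mk_reps(list(noise, n2, n3))), "discordant")
})

test_that("averaging is an unweighted mean over retained replicates", {
  rep_scores <- data.frame(
    variant_id = c("A1C", "A1C", "A2C"),
    construct = "FL", condition = "k", tile = 1L,
    replicate = c(1L, 2L, 1L),
    score = c(1.0, 3.0, 5.0),
    flagged = FALSE, stringsAsFactors = FALSE
  )
  st <- average_scores(rep_scores)
  expect_equal(st$score[st$variant_id == "A1C"], 2.0)
  expect_equal(st$n_reps[st$variant_id == "A1C"], 2L)
  expect_equal(st$score[st$variant_id == "A2C"], 5.0)  # single replicate
  expect_equal(st$n_reps[st$variant_id == "A2C"], 1L)
  expect_equal(st$position, c(1L, 2L))
})

test_that("emit_reads -> count_reads round-trips the count table exactly", {
  s <- small_sim(length = 10, depth = 400, n_replicates = 2)
  dir <- withr::local_tempdir()
  manifest <- emit_reads(s$sim, s$ref, dir)
  expect_equal(nrow(manifest), nrow(s$sim$tiles) * 2 * 2)
  counted <- count_reads(manifest, s$ref, "FL", s$sim$tiles,
                         condition = "cSrc_KD")
  key <- function(d) paste(d$variant_id, d$tile, d$replicate, d$timepoint)
  a <- s$sim$counts[order(key(s$sim$counts)), ]
  b <- counted[order(key(counted)), ]
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$count, b$count)
  expect_equal(key(a), key(b))
  expect_equal(sum(attr(counted, "discards")$discarded), 0L)

  ## a read carrying two mutated codons is discarded, not miscounted
  fq <- manifest$path[manifest$tile == 1 & manifest$replicate == 1 &
                        manifest$timepoint == "pre"]
  dict <- shp2dms:::tile_sequence_dictionary(s$ref, "FL", s$sim$tiles, 1)
  wt_seq <- names(dict)[dict == "WT"]
  doubled <- wt_seq
  substr(doubled, 1, 6) <- "GCCGCC"
  stopifnot(doubled != wt_seq)
  cat(sprintf("@double\n%s\n+\n%s\n", doubled, strrep("I", nchar(doubled))),
      file = fq, append = TRUE)
  recount <- count_reads(manifest[manifest$path == fq, ], s$ref, "FL",
                         s$sim$tiles)
  expect_equal(sum(attr(recount, "discards")$discarded), 1L)
  expect_equal(sum(recount$count),
               sum(b$count[b$tile == 1 & b$replicate == 1 &
                             b$timepoint == "pre"]))
})

test_that("scores track the true activity ordering on simulated data", {
  ref <- toy_reference(length = 100, seed = 21)
  gt <- plant_landscape(ref, seed = 22)
  run_at <- function(depth) {
    cfg <- selection_config("cSrc_KD", depth_pre = depth, depth_post = depth,
                            n_replicates = 3, seed = 23)
    sim <- simulate_selection(gt, ref, "FL", cfg)
    st <- average_scores(enrichment_scores(sim$counts))
    truth <- sim$truth
    list(score = st$score,
         expected = truth$expected_score[match(st$variant_id,
                                               truth$variant_id)])
  }
  r5 <- run_at(1e5)
  expect_gte(cor(r5$score, r5$expected, method = "spearman"), 0.9)
  r6 <- run_at(1e6)
  expect_gte(cor(r6$score, r6$expected, method = "spearman"), 0.95)
})

test_that("heatmap matrices mask WT and missing cells distinctly", {
  ref <- protein_reference("tri", "ATGGCTGGT")  # M A G
  scores <- data.frame(
    variant_id = c("M1A", "A2C", "G3W"),
    position = c(1L, 2L, 3L), wt_aa = c("M", "A", "G"),
    mut_aa = c("A", "C", "W"), construct = "FL", condition = "k",
    score = c(0.5, -1, 2), n_reps = 2L, stringsAsFactors = FALSE
  )
  hm <- heatmap_matrix(scores, ref)
  expect_equal(dim(hm$score), c(3L, 20L))
  expect_equal(sum(hm$mask == "wt"), 3L)
  expect_equal(hm$mask["1", "M"], "wt")
  ## values round-trip to the table; absences are masked, not zero
  expect_equal(hm$score["2", "C"], -1)
  expect_true(is.na(hm$score["2", "D"]))
  expect_equal(hm$mask["2", "D"], "missing")
  expect_equal(sum(hm$mask == "ok"), 3L)
  dup <- rbind(scores, scores[1, ])
  expect_error(heatmap_matrix(dup, ref), "duplicate")
})

test_that("site summaries average within positions and classify sites", {
  scores <- data.frame(
    variant_id = c("M1A", "M1C", "A2C", "A2D"),
    position = c(1L, 1L, 2L, 2L), wt_aa = c("M", "M", "A", "A"),
    mut_aa = c("A", "C", "C", "D"), construct = "FL", condition = "k",
    score = c(2, 2, 1.5, -1.5), n_reps = 2L, stringsAsFactors = FALSE
  )
  ss <- site_summary(scores, activate_cut = 1, deactivate_cut = -1)
  expect_equal(ss$mean_score, c(2, 0))  # group-by means
  expect_equal(ss$site_class, c("activating", "neutral"))
  ## matches a direct group-by oracle on a fuzzed table
  set.seed(4)
  scores$score <- rnorm(4)
  ss2 <- site_summary(scores)
  oracle <- tapply(scores$score, scores$position, mean)
  expect_equal(ss2$mean_score, as.numeric(oracle))
  expect_error(site_summary(scores, activate_cut = -1, deactivate_cut = -2),
               "deactivate_cut < 0")
})
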