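## Enrichment scoring: reads/counts -> WT-normalized log2 scores,
## replicate QC, averaging, heatmap matrices, per-site summaries.

#' Count exact-match reads into a count table
#'
#' Assigns each tile-length read to the wild-type tile sequence or to one
#' of the expected single-codon variants of its tile by exact sequence
#' match. Reads of the wrong length or not matching any library member
#' (e.g. carrying two mutated codons) are tallied as discards, never
#' counted. Counts are dense: every expected library member of a tile
#' gets a row, with 0 where unobserved.
#'
#' @param manifest data.frame with columns `path`, `tile`, `replicate`,
#'   `timepoint` (as returned by [emit_reads()]).
#' @param ref The [protein_reference()].
#' @param construct `"FL"` or `"PTP"`.
#' @param tiles The [tile_sequence()] table used for the reads.
#' @param condition Condition label to stamp on the rows.
#' @param include_stop Does the expected library include nonsense
#'   variants? Must match how the library was designed, or legitimate
#'   reads end up in the discard tally (or vice versa).
#' @return Count data.frame (same shape as [simulate_selection()]'s
#'   `counts`), with attribute `discards` (data.frame per file).
#' @export
count_reads <- function(manifest, ref, construct = c("FL", "PTP"), tiles,
                        condition = "unknown", include_stop = FALSE) {
  construct <- match.arg(construct)
  out <- vector("list", nrow(manifest))
  discards <- integer(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    t <- manifest$tile[i]
    dict <- tile_sequence_dictionary(ref, construct, tiles, t, include_stop)
    reads <- tryCatch(
      as.character(Biostrings::readDNAStringSet(manifest$path[i],
                                                format = "fastq")),
      error = function(e) character(0)
    )
    hit <- dict[reads]  # NA where unmatched (incl. wrong length)
    discards[i] <- sum(is.na(hit))
    tab <- table(factor(hit[!is.na(hit)], levels = unname(dict)))
    out[[i]] <- data.frame(
      variant_id = names(tab),
      construct = construct,
      condition = condition,
      tile = t,
      replicate = manifest$replicate[i],
      timepoint = manifest$timepoint[i],
      count = as.numeric(tab),
      stringsAsFactors = FALSE
    )
  }
  counts <- do.call(rbind, out)
  attr(counts, "discards") <- cbind(manifest, discarded = discards)
  counts
}

#' Per-replicate wild-type-normalized enrichment scores
#'
#' Within each (tile, replicate):
#' `score_v = log2((post_v + p) / (pre_v + p)) -
#'            log2((post_WT + p) / (pre_WT + p))`,
#' the standard ratio-of-ratios estimator against the tile-internal
#' wild-type. The wild-type row itself scores exactly 0 in every tile and
#' replicate by construction. Variants with fewer than `min_reads`
#' pre-selection reads are flagged (`flagged = TRUE`) and should be
#' treated as missing for that replicate.
#'
#' @param counts Count data.frame (see [simulate_selection()]).
#' @param pseudocount Pseudocount `p` added to every count (default 0.5).
#' @param min_reads Minimum pre-selection reads per variant (default 10).
#' @return data.frame: `variant_id`, `construct`, `condition`, `tile`,
#'   `replicate`, `pre`, `post`, `score`, `flagged`.
#' @export
enrichment_scores <- function(counts, pseudocount = 0.5, min_reads = 10) {
  pre <- counts[counts$timepoint == "pre", ]
  post <- counts[counts$timepoint == "post", ]
  key <- function(d) paste(d$construct, d$condition, d$tile, d$replicate,
                           d$variant_id, sep = "\r")
  merged <- pre[c("variant_id", "construct", "condition", "tile", "replicate")]
  merged$pre <- pre$count
  idx <- match(key(pre), key(post))
  if (anyNA(idx)) stop("pre/post rows do not pair up; malformed count table")
  merged$post <- post$count[idx]

  grp <- paste(merged$construct, merged$condition, merged$tile,
               merged$replicate, sep = "\r")
  wt_rows <- merged$variant_id == "WT"
  wt_by_grp <- merged[wt_rows, ]
  if (any(!unique(grp) %in% grp[wt_rows])) {
    stop("WT row absent in some (tile, replicate); cannot normalize")
  }
  wt_idx <- match(grp, grp[wt_rows])
  wt_pre <- wt_by_grp$pre[wt_idx]
  wt_post <- wt_by_grp$post[wt_idx]

  p <- pseudocount
  merged$score <- (log2(merged$post + p) - log2(merged$pre + p)) -
    (log2(wt_post + p) - log2(wt_pre + p))
  merged$score[wt_rows] <- 0  # exact, not up to float error
  merged$flagged <- merged$pre < min_reads & !wt_rows
  merged
}

#' Replicate concordance QC
#'
#' Computes the pairwise Pearson correlation of per-replicate scores over
#' shared, unflagged variants, and drops replicates that are discordant
#' with the rest: a replicate is retained when it correlates at
#' `r >= min_pearson_r` with at least one other replicate, so a lone
#' noise replicate (concordant with nothing) is dropped while the
#' mutually concordant majority survives. With exactly two replicates
#' both are retained if they pass the threshold against each other and an
#' error is raised otherwise. If fewer than two replicates would survive,
#' an error with the correlation diagnostics is raised.
#'
#' @param rep_scores Output of [enrichment_scores()] (one construct and
#'   condition at a time).
#' @param min_pearson_r Retention threshold (default 0.6).
#' @return List: `retained` (integer replicate ids), `dropped`,
#'   `cor_matrix`.
#' @export
replicate_qc <- function(rep_scores, min_pearson_r = 0.6) {
  rs <- rep_scores[rep_scores$variant_id != "WT" & !rep_scores$flagged, ]
  reps <- sort(unique(rs$replicate))
  if (length(reps) < 2L) stop("replicate_qc needs >= 2 replicates")
  wide <- matrix(NA_real_, nrow = length(unique(rs$variant_id)),
                 ncol = length(reps),
                 dimnames = list(unique(rs$variant_id), paste0("rep", reps)))
  wide[cbind(match(rs$variant_id, rownames(wide)),
             match(rs$replicate, reps))] <- rs$score
  cm <- stats::cor(wide, use = "pairwise.complete.obs")
  off <- cm
  diag(off) <- NA
  best_r <- apply(off, 1, max, na.rm = TRUE)
  retained <- reps[best_r >= min_pearson_r]
  if (length(reps) == 2L && length(retained) < 2L) {
    stop("two replicates are discordant (r = ", signif(cm[1, 2], 3),
         " < ", min_pearson_r, "); no majority to arbitrate")
  }
  if (length(retained) < 2L) {
    stop("replicates are mutually discordant; best pairwise r: ",
         paste(signif(best_r, 3), collapse = ", "))
  }
  list(retained = retained, dropped = setdiff(reps, retained),
       cor_matrix = cm)
}

#' Average replicate scores into a score table
#'
#' Unweighted mean of unflagged replicate scores per variant, restricted
#' to retained replicates. Variants with no usable replicate are omitted
#' (missing, never imputed).
#'
#' @param rep_scores Output of [enrichment_scores()].
#' @param retained Replicate ids to use (default: all present).
#' @param include_wt Keep the `"WT"` rows (score 0)? Default drops them.
#' @return data.frame of class `score_table`: `variant_id`, `position`,
#'   `wt_aa`, `mut_aa`, `construct`, `condition`, `score`, `n_reps`.
#' @export
average_scores <- function(rep_scores, retained = NULL, include_wt = FALSE) {
  rs <- rep_scores[!rep_scores$flagged, ]
  if (!is.null(retained)) rs <- rs[rs$replicate %in% retained, ]
  if (!include_wt) rs <- rs[rs$variant_id != "WT", ]
  if (nrow(rs) == 0L) stop("no usable replicate scores")
  agg <- stats::aggregate(score ~ variant_id + construct + condition, data = rs,
                          FUN = mean)
  n <- stats::aggregate(score ~ variant_id + construct + condition, data = rs,
                        FUN = length)
  agg$n_reps <- n$score  # aggregate() row order is identical for both calls
  non_wt <- agg$variant_id != "WT"
  meta <- parse_variant_id(agg$variant_id[non_wt])
  agg$position <- NA_integer_
  agg$wt_aa <- NA_character_
  agg$mut_aa <- NA_character_
  agg$position[non_wt] <- meta$position
  agg$wt_aa[non_wt] <- meta$wt_aa
  agg$mut_aa[non_wt] <- meta$mut_aa
  out <- agg[order(agg$position, agg$mut_aa),
             c("variant_id", "position", "wt_aa", "mut_aa", "construct",
               "condition", "score", "n_reps")]
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  out
}

#' Position-by-substitution score matrix for heatmaps
#'
#' @param scores A [average_scores()] table (one construct).
#' @param ref The [protein_reference()].
#' @param aa_order Row order of substitutions (default [aa_alphabet()]
#'   with `*` last when stops are present).
#' @return List: `score` (positions x substitutions matrix, `NA` where
#'   masked) and `mask` (character matrix: `"ok"`, `"wt"`, `"missing"`).
#' @export
heatmap_matrix <- function(scores, ref, aa_order = NULL) {
  if (anyDuplicated(scores$variant_id)) stop("duplicate variant rows")
  construct <- unique(scores$construct)
  if (length(construct) != 1L) stop("heatmap_matrix expects one construct")
  rng <- construct_range(ref, construct)
  positions <- seq.int(rng[1], rng[2])
  if (is.null(aa_order)) {
    aa_order <- aa_alphabet(include_stop = any(scores$mut_aa == "*"))
  }
  m <- matrix(NA_real_, nrow = length(positions), ncol = length(aa_order),
              dimnames = list(positions, aa_order))
  mask <- matrix("missing", nrow = length(positions), ncol = length(aa_order),
                 dimnames = list(positions, aa_order))
  wt <- strsplit(substr(ref$aa, rng[1], rng[2]), "")[[1]]
  mask[cbind(seq_along(positions), match(wt, aa_order))] <- "wt"
  ri <- match(scores$position, positions)
  ci <- match(scores$mut_aa, aa_order)
  keep <- !is.na(ri) & !is.na(ci)
  m[cbind(ri[keep], ci[keep])] <- scores$score[keep]
  mask[cbind(ri[keep], ci[keep])] <- "ok"
  list(score = m, mask = mask)
}

#' Per-site mean scores and site classes
#'
#' Mean score over the non-missing substitutions at each position, with a
#' site called `activating` when the mean exceeds `activate_cut`,
#' `inactivating` below `deactivate_cut`, else `neutral`.
#'
#' @param scores A [average_scores()] table.
#' @param activate_cut,deactivate_cut Thresholds on the site mean
#'   (`deactivate_cut < 0 < activate_cut`).
#' @return data.frame: `position`, `n`, `mean_score`, `site_class`.
#' @export
site_summary <- function(scores, activate_cut = 1, deactivate_cut = -1) {
  if (!(deactivate_cut < 0 && 0 < activate_cut)) {
    stop("need deactivate_cut < 0 < activate_cut")
  }
  agg <- stats::aggregate(score ~ position, data = scores, FUN = mean)
  n <- stats::aggregate(score ~ position, data = scores, FUN = length)
  cls <- ifelse(agg$score > activate_cut, "activating",
                ifelse(agg$score < deactivate_cut, "inactivating", "neutral"))
  data.frame(position = agg$position, n = n$score, mean_score = agg$score,
             site_class = cls, stringsAsFactors = FALSE)
}

#' Write / read a score table as TSV
#'
#' @param scores A [average_scores()] table.
#' @param path File path.
#' @return `write_score_table`: the path, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}
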