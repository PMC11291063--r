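## Growth-rescue selection simulator with a planted mechanistic landscape.
##
## The latent model has two axes per variant: alpha, the intrinsic
## catalytic activity multiplier of the phosphatase domain (wild type = 1),
## and phi, the open (non-auto-inhibited) fraction in the full-length
## context (wild type = phi_wt, default 0.05). Full-length activity is
## alpha * phi; the isolated catalytic domain is always open, so its
## activity is alpha. Growth under kinase pressure follows a Hill function
## of activity, and sequencing counts are multinomial at finite depth.

#' Default mechanistic class mix of the planted landscape
#'
#' Six classes mirror the mechanisms resolved by the two-construct
#' comparison: `neutral` (near-wild-type), `catalytic_dead` (alpha near
#' 0), `autoinhibition_release` (phi driven toward 1, alpha near 1),
#' `dual_activating` (alpha > 1 and phi near 1), `interface_stabilizing`
#' (phi pushed below phi_wt, alpha near 1) and `catalytic_up` (alpha > 1,
#' phi unchanged). Most single substitutions in a large multi-domain
#' protein are near-neutral in a growth assay, so the default mix is
#' dominated by the neutral class with a few percent in each mechanistic
#' class.
#'
#' @return Named numeric vector of class fractions summing to 1.
#' @export
default_class_fractions <- function() {
  c(neutral = 0.88,
    catalytic_dead = 0.03,
    autoinhibition_release = 0.03,
    dual_activating = 0.02,
    interface_stabilizing = 0.02,
    catalytic_up = 0.02)
}

#' Default effect distributions per mechanistic class
#'
#' `alpha` is log-normal per class; `phi` is either pinned at `phi_wt`,
#' drawn as `phi_wt + (1 - phi_wt) * Beta(shape1, shape2)` (release
#' classes, mass near 1), or `phi_wt * Beta(shape1, shape2)`
#' (interface-stabilizing, mass well below `phi_wt`).
#'
#' @return Named list of per-class parameter lists.
#' @export
default_class_params <- function() {
  list(
    neutral = list(alpha_meanlog = 0, alpha_sdlog = 0.10, phi = "wt"),
    catalytic_dead = list(alpha_meanlog = log(0.005), alpha_sdlog = 0.5,
                          phi = "wt"),
    autoinhibition_release = list(alpha_meanlog = 0, alpha_sdlog = 0.10,
                                  phi = "release",
                                  phi_shape1 = 10, phi_shape2 = 2),
    dual_activating = list(alpha_meanlog = log(3), alpha_sdlog = 0.15,
                           phi = "release",
                           phi_shape1 = 10, phi_shape2 = 2),
    interface_stabilizing = list(alpha_meanlog = 0, alpha_sdlog = 0.10,
                                 phi = "stabilize",
                                 phi_shape1 = 2, phi_shape2 = 18),
    catalytic_up = list(alpha_meanlog = log(3), alpha_sdlog = 0.15,
                        phi = "wt")
  )
}

#' Plant a ground-truth mutational landscape
#'
#' Assigns every enumerated variant a mechanistic class and draws its
#' latent effects (alpha, phi) from that class's distributions.
#' Deterministic given `seed`.
#'
#' @param ref A [protein_reference()].
#' @param class_fractions Named fractions summing to 1 (see
#'   [default_class_fractions()]).
#' @param class_params Per-class distributions (see
#'   [default_class_params()]).
#' @param phi_wt Wild-type open fraction in the full-length context.
#' @param include_stop Plant effects for nonsense variants too?
#' @param seed Integer seed.
#' @return data.frame of class `ground_truth` with one row per variant:
#'   `variant_id`, `position`, `wt_aa`, `mut_aa`, `class`, `alpha`,
#'   `phi`, `expression`; `phi_wt` is carried as an attribute.
#' @export
plant_landscape <- function(ref,
                            class_fractions = default_class_fractions(),
                            class_params = default_class_params(),
                            phi_wt = 0.05,
                            include_stop = FALSE,
                            seed = 1L) {
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must sum to 1")
  }
  if (!all(names(class_fractions) %in% names(class_params))) {
    stop("class_fractions names must match class_params")
  }
  variants <- enumerate_variants(ref, "FL", include_stop = include_stop)
  n <- nrow(variants)
  set.seed(seed)
  cls <- sample(names(class_fractions), n, replace = TRUE,
                prob = unname(class_fractions))
  alpha <- numeric(n)
  phi <- numeric(n)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    p <- class_params[[cl]]
    alpha[idx] <- stats::rlnorm(length(idx), p$alpha_meanlog, p$alpha_sdlog)
    phi[idx] <- switch(p$phi,
      wt = rep.int(phi_wt, length(idx)),
      release = phi_wt + (1 - phi_wt) *
        stats::rbeta(length(idx), p$phi_shape1, p$phi_shape2),
      stabilize = phi_wt * stats::rbeta(length(idx), p$phi_shape1, p$phi_shape2),
      stop("unknown phi rule: ", p$phi)
    )
  }
  gt <- cbind(variants[c("variant_id", "position", "wt_aa", "mut_aa")],
              data.frame(class = cls, alpha = alpha, phi = phi,
                         expression = 1, stringsAsFactors = FALSE))
  attr(gt, "phi_wt") <- phi_wt
  class(gt) <- c("ground_truth", "data.frame")
  gt
}

#' Latent activity of each variant in a construct context
#'
#' Full-length activity is `alpha * phi` (catalysis gated by the open
#' fraction); the isolated catalytic domain is fully open, so its activity
#' is `alpha`. Activities are on the scale where a fully open wild-type
#' domain has activity 1, so wild type scores `phi_wt` in FL and 1 in PTP.
#'
#' @param gt A [plant_landscape()] table.
#' @param construct `"FL"` or `"PTP"`.
#' @return Numeric vector of activities, one per `gt` row.
#' @export
construct_activity <- function(gt, construct = c("FL", "PTP")) {
  construct <- match.arg(construct)
  if (construct == "FL") gt$alpha * gt$phi else gt$alpha
}

#' Wild-type activity in a construct context
#'
#' @param construct `"FL"` or `"PTP"`.
#' @param phi_wt Wild-type open fraction.
#' @return Scalar activity.
#' @export
wildtype_activity <- function(construct = c("FL", "PTP"), phi_wt = 0.05) {
  construct <- match.arg(construct)
  if (construct == "FL") phi_wt else 1
}

#' Selection configuration
#'
#' Parameters of one selection condition. The two kinase pressures differ
#' in `K_half`, the activity needed for half-maximal growth: the highly
#' active full-length viral Src (`vSrc_FL`, `K_half = 0.5`) demands much
#' more phosphatase activity than the weaker isolated c-Src kinase domain
#' (`cSrc_KD`, `K_half = 0.05`), which is what gives the two assays their
#' different dynamic ranges.
#'
#' @param kinase `"cSrc_KD"` or `"vSrc_FL"`.
#' @param K_half Activity at half-maximal growth; kinase-dependent default.
#' @param hill Hill coefficient of the growth response.
#' @param g_max Maximal growth rate, divisions/hour.
#' @param T_outgrowth Outgrowth time in hours (default 24).
#' @param depth_pre,depth_post Total sequencing reads per tile and
#'   timepoint.
#' @param n_replicates Number of replicate selections (2-4 typical).
#' @param library_skew_sdlog Log-normal sd of per-replicate library skew.
#' @param wt_weight Relative pre-selection abundance of the wild-type
#'   sequence in each tile (variants have weight `expression`, i.e. 1).
#' @param seed Master seed; per-(tile, replicate, timepoint) streams are
#'   derived from it by a fixed counter.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(kinase = c("cSrc_KD", "vSrc_FL"),
                             K_half = NULL,
                             hill = 2,
                             g_max = 0.35,
                             T_outgrowth = 24,
                             depth_pre = 1e5,
                             depth_post = 1e5,
                             n_replicates = 3L,
                             library_skew_sdlog = 0.3,
                             wt_weight = 10,
                             seed = 1L) {
  kinase <- match.arg(kinase)
  if (is.null(K_half)) {
    K_half <- switch(kinase, cSrc_KD = 0.05, vSrc_FL = 0.5)
  }
  stopifnot(K_half > 0, hill > 0, g_max > 0, T_outgrowth > 0,
            depth_pre > 0, depth_post > 0, n_replicates >= 1,
            wt_weight > 0)
  structure(list(kinase = kinase, K_half = K_half, hill = hill,
                 g_max = g_max, T_outgrowth = T_outgrowth,
                 depth_pre = depth_pre, depth_post = depth_post,
                 n_replicates = as.integer(n_replicates),
                 library_skew_sdlog = library_skew_sdlog,
                 wt_weight = wt_weight, seed = as.integer(seed)),
            class = "selection_config")
}

#' Growth rate as a Hill function of phosphatase activity
#'
#' `g(a) = g_max * a^h / (a^h + K_half^h)`: zero at zero activity,
#' monotone non-decreasing, half-maximal at `a = K_half`.
#'
#' @param activity Non-negative activity (vectorized).
#' @param cfg A [selection_config()].
#' @return Growth rate in divisions/hour.
#' @export
growth_rate <- function(activity, cfg) {
  if (any(activity < 0)) stop("activity must be >= 0")
  ah <- activity^cfg$hill
  cfg$g_max * ah / (ah + cfg$K_half^cfg$hill)
}

#' Expected log2 enrichment of a variant relative to a reference activity
#'
#' In the noiseless limit of the model, a variant's post/pre abundance
#' ratio is `2^(g * T)`, so its wild-type-normalized log2 enrichment is
#' `(g(a) - g(a_ref)) * T`.
#'
#' @param activity Variant activity (vectorized).
#' @param ref_activity Wild-type activity in the same construct context.
#' @param cfg A [selection_config()].
#' @return Expected log2 enrichment score.
#' @export
expected_enrichment <- function(activity, ref_activity, cfg) {
  (growth_rate(activity, cfg) - growth_rate(ref_activity, cfg)) *
    cfg$T_outgrowth
}

#' Sensitivity of expected enrichment to log-activity
#'
#' The derivative `d(score)/d(ln activity) = T * g_max * h * a^h * K^h /
#' (a^h + K^h)^2`, which peaks at `a = K_half`. Under the strong-kinase
#' pressure (larger `K_half`) the assay is therefore most discriminating
#' among high-activity variants, and under the weak-kinase pressure among
#' low-activity variants.
#'
#' @param activity Activity grid (vectorized, > 0).
#' @param cfg A [selection_config()].
#' @return Sensitivity in score units per natural-log activity unit.
#' @export
enrichment_sensitivity <- function(activity, cfg) {
  ah <- activity^cfg$hill
  kh <- cfg$K_half^cfg$hill
  cfg$T_outgrowth * cfg$g_max * cfg$hill * ah * kh / (ah + kh)^2
}

## Derived RNG stream: fixed counter over (construct, tile, replicate, phase).
## phase: 0 = library skew, 1 = pre sampling, 2 = post sampling.
stream_seed <- function(master, construct, tile, replicate, phase) {
  off <- (if (construct == "FL") 0L else 1L) * 499979L +
    tile * 7919L + replicate * 613L + phase * 97L
  (as.integer(master) + off) %% .Machine$integer.max
}

#' Simulate a growth-rescue selection and emit count tables
#'
#' For each tile and replicate: pre-selection abundances are the planted
#' expression weights times a seeded log-normal library skew; the pool
#' grows exponentially for `T_outgrowth` hours at the Hill growth rate of
#' each variant's activity; pre and post pools are sequenced as
#' independent multinomial draws at the configured depths. A wild-type
#' row (abundance weight `wt_weight`) is present in every tile. With
#' `exact = TRUE`, counts are the exact (non-integer) expectations at the
#' configured depth - the infinite-depth limit used for noiseless checks.
#'
#' @param gt A [plant_landscape()] table.
#' @param ref The [protein_reference()] the landscape was planted on.
#' @param construct `"FL"` or `"PTP"`; only variants inside the construct
#'   window are simulated, with tile positions local to the window.
#' @param cfg A [selection_config()].
#' @param tiles Optional [tile_sequence()] table over the construct
#'   window; defaults to the 42-codon ceiling partition.
#' @param exact Emit exact expected counts instead of multinomial draws?
#' @return List of class `selection_sim`: `counts` (long data.frame:
#'   `variant_id` incl. `"WT"`, `construct`, `condition`, `tile`,
#'   `replicate`, `timepoint`, `count`), `truth` (per-variant sidecar with
#'   `activity` and `expected_score`), `tiles`, `cfg`.
#' @export
simulate_selection <- function(gt, ref, construct = c("FL", "PTP"), cfg,
                               tiles = NULL, exact = FALSE) {
  construct <- match.arg(construct)
  rng <- construct_range(ref, construct)
  if (is.null(tiles)) tiles <- tile_sequence(rng[2] - rng[1] + 1L)
  gtc <- gt[gt$position >= rng[1] & gt$position <= rng[2], , drop = FALSE]
  if (nrow(gtc) == 0L) stop("no variants inside the ", construct, " window")
  local_pos <- gtc$position - rng[1] + 1L
  tile_idx <- assign_tiles(local_pos, tiles)
  phi_wt <- attr(gt, "phi_wt")

  act <- construct_activity(gtc, construct)
  act_wt <- wildtype_activity(construct, phi_wt)
  grow <- 2^(growth_rate(act, cfg) * cfg$T_outgrowth)
  grow_wt <- 2^(growth_rate(act_wt, cfg) * cfg$T_outgrowth)

  out <- vector("list", nrow(tiles) * cfg$n_replicates)
  k <- 0L
  for (t in seq_len(nrow(tiles))) {
    in_tile <- tile_idx == t
    if (!any(in_tile)) stop("tile ", t, " contains no variants")
    ids <- c("WT", gtc$variant_id[in_tile])
    base_w <- c(cfg$wt_weight, gtc$expression[in_tile])
    g2 <- c(grow_wt, grow[in_tile])
    for (r in seq_len(cfg$n_replicates)) {
      set.seed(stream_seed(cfg$seed, construct, t, r, 0L))
      skew <- stats::rlnorm(length(ids), 0, cfg$library_skew_sdlog)
      pre_w <- base_w * skew
      post_w <- pre_w * g2
      if (exact) {
        pre_counts <- cfg$depth_pre * pre_w / sum(pre_w)
        post_counts <- cfg$depth_post * post_w / sum(post_w)
      } else {
        set.seed(stream_seed(cfg$seed, construct, t, r, 1L))
        pre_counts <- as.numeric(stats::rmultinom(1, cfg$depth_pre,
                                                  pre_w / sum(pre_w)))
        set.seed(stream_seed(cfg$seed, construct, t, r, 2L))
        post_counts <- as.numeric(stats::rmultinom(1, cfg$depth_post,
                                                   post_w / sum(post_w)))
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        variant_id = rep.int(ids, 2L),
        construct = construct,
        condition = cfg$kinase,
        tile = t,
        replicate = r,
        timepoint = rep(c("pre", "post"), each = length(ids)),
        count = c(pre_counts, post_counts),
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- cbind(gtc,
                 data.frame(construct = construct,
                            activity = act,
                            expected_score = expected_enrichment(act, act_wt, cfg),
                            tile = tile_idx))
  structure(list(counts = do.call(rbind, out), truth = truth,
                 tiles = tiles, cfg = cfg, construct = construct),
            class = "selection_sim")
}

## First codon (alphabetically) encoding an amino acid; '*' allowed.
designed_codon <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  vapply(aa, function(a) {
    hits <- sort(names(gc)[gc == a])
    if (length(hits) == 0L) stop("no codon encodes '", a, "'")
    hits[1]
  }, character(1), USE.NAMES = FALSE)
}

## Tile DNA sequences for WT and for every expected variant of a tile.
## Returns named character vector: names are sequences, values variant ids.
tile_sequence_dictionary <- function(ref, construct, tiles, tile,
                                     include_stop = FALSE) {
  rng <- construct_range(ref, construct)
  row <- tiles[tiles$tile == tile, ]
  gstart <- rng[1] + row$start_codon - 1L  # global first codon of tile
  gend <- rng[1] + row$end_codon - 1L
  wt_dna <- substr(ref$cds, 3L * (gstart - 1L) + 1L, 3L * gend)
  variants <- enumerate_variants(ref, construct, include_stop = include_stop)
  variants <- variants[variants$position >= gstart & variants$position <= gend, ]
  offs <- 3L * (variants$position - gstart)  # 0-based nt offset within tile
  codons <- designed_codon(variants$mut_aa)
  seqs <- vapply(seq_len(nrow(variants)), function(i) {
    s <- wt_dna
    substr(s, offs[i] + 1L, offs[i] + 3L) <- codons[i]
    s
  }, character(1))
  ## A designed codon can coincide with the WT codon only for synonymous
  ## changes, which are excluded (mut_aa != wt_aa), so seqs are unique.
  stats::setNames(c("WT", variants$variant_id), c(wt_dna, seqs))
}

#' Expand a count table into error-free FASTQ reads
#'
#' Each count becomes that many tile-length reads carrying the variant's
#' designed mutant codon (one fixed codon per substitution, the
#' alphabetically first codon of the mutant amino acid); wild-type counts
#' become reads of the reference tile. Qualities are constant Phred 40
#' (`I`). One FASTQ file per (tile, replicate, timepoint).
#'
#' @param sim A [simulate_selection()] result (non-`exact`).
#' @param ref The matching [protein_reference()].
#' @param dir Output directory (created if needed).
#' @return data.frame manifest with columns `path`, `tile`, `replicate`,
#'   `timepoint`.
#' @export
emit_reads <- function(sim, ref, dir) {
  counts <- sim$counts
  if (any(counts$count != round(counts$count))) {
    stop("emit_reads needs integer counts (exact = FALSE simulations)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  m <- 0L
  for (t in unique(counts$tile)) {
    dict <- tile_sequence_dictionary(ref, sim$construct, sim$tiles, t)
    seq_of <- stats::setNames(names(dict), dict)  # variant_id -> sequence
    sub_t <- counts[counts$tile == t, ]
    for (r in unique(sub_t$replicate)) {
      for (tp in c("pre", "post")) {
        rows <- sub_t[sub_t$replicate == r & sub_t$timepoint == tp, ]
        rows <- rows[rows$count > 0, ]
        seqs <- rep(seq_of[rows$variant_id], times = rows$count)
        ids <- paste0(rep(rows$variant_id, times = rows$count), "_",
                      sequence(rows$count))
        path <- file.path(dir, sprintf("tile%02d_rep%d_%s.fastq", t, r, tp))
        x <- Biostrings::DNAStringSet(unname(seqs))
        names(x) <- ids
        qual <- Biostrings::PhredQuality(
          unname(vapply(nchar(seqs), function(n) strrep("I", n), character(1)))
        )
        xq <- Biostrings::QualityScaledDNAStringSet(x, qual)
        Biostrings::writeQualityScaledXStringSet(xq, path)
        m <- m + 1L
        manifest[[m]] <- data.frame(path = path, tile = t, replicate = r,
                                    timepoint = tp, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, manifest)
}

#' Emit a synthetic clinical-annotation table
#'
#' Samples variants into disease groups with class-conditional biases,
#' emulating the structure (not the content) of ClinVar/COSMIC/TCGA-style
#' records. Each group restricts which mechanistic classes it may draw
#' from - e.g. a liver-like group drawn only from neutral and
#' loss-of-activity classes - so group-level score summaries have a known
#' expected direction.
#'
#' @param gt A [plant_landscape()] table.
#' @param groups Named list; each element is a list with `n` (number of
#'   annotated variants) and `classes` (allowed class labels, `NULL` =
#'   any). See the default for the shape.
#' @param pathogenic_frac Probability an annotation is labelled
#'   `pathogenic` (remainder split between `VUS` and `benign`).
#' @param seed Integer seed.
#' @return data.frame with columns `variant_id`, `source`,
#'   `pathogenicity`, `disease_group`, `case_count`.
#' @export
emit_annotations <- function(gt,
                             groups = list(
                               blood = list(n = 60, classes = c(
                                 "autoinhibition_release", "dual_activating",
                                 "catalytic_up")),
                               liver = list(n = 25, classes = c(
                                 "neutral", "catalytic_dead",
                                 "interface_stabilizing")),
                               skin = list(n = 30, classes = NULL),
                               colon = list(n = 30, classes = NULL)
                             ),
                             pathogenic_frac = 0.25,
                             seed = 1L) {
  set.seed(seed)
  out <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    pool <- if (is.null(g$classes)) gt else gt[gt$class %in% g$classes, ]
    if (nrow(pool) == 0L) next
    n <- min(g$n, nrow(pool))
    pick <- pool$variant_id[sample.int(nrow(pool), n)]
    path_lab <- sample(c("pathogenic", "VUS", "benign"), n, replace = TRUE,
                       prob = c(pathogenic_frac,
                                (1 - pathogenic_frac) * 0.7,
                                (1 - pathogenic_frac) * 0.3))
    out[[gname]] <- data.frame(
      variant_id = pick,
      source = sample(c("ClinVar-like", "COSMIC-like"), n, replace = TRUE),
      pathogenicity = path_lab,
      disease_group = gname,
      case_count = 1L + stats::rpois(n, 2),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write / read a count table as TSV
#'
#' @param counts Count data.frame (see [simulate_selection()]).
#' @param path File path.
#' @return `write_count_table`: the path, invisibly.
#' @export
write_count_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
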