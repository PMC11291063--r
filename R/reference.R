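## Reference sequences, variant enumeration, genetic-code utilities.

#' Standard amino-acid alphabet
#'
#' Fixed, alphabetical one-letter amino-acid order used throughout the
#' package (heatmap rows, variant enumeration). The stop symbol `*`, when
#' requested, always comes last.
#'
#' @param include_stop Include the stop symbol `*` as the final element?
#' @return Character vector of length 20 (or 21 with `*`).
#' @export
aa_alphabet <- function(include_stop = FALSE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (include_stop) c(aa, "*") else aa
}

#' Protein/CDS reference with construct windows
#'
#' Bundles a protein sequence, its coding DNA, and the residue windows that
#' define the two screened constructs: the full-length protein (`FL`,
#' always `1..L`) and the isolated catalytic domain (`PTP`, a contiguous
#' window). The CDS must translate exactly to the protein sequence under
#' the standard genetic code and carries no stop codon.
#'
#' @param name Reference name.
#' @param cds Coding DNA string (A/C/G/T, length `3 * L`).
#' @param aa_sequence Optional protein sequence; derived from `cds` when
#'   omitted, checked against the translation when given.
#' @param ptp_range Optional length-2 integer vector, the inclusive 1-based
#'   residue window of the isolated catalytic-domain construct.
#' @return An object of class `protein_reference` with fields `name`,
#'   `aa`, `cds` and `windows` (named list of `c(start, end)`).
#' @export
protein_reference <- function(name, cds, aa_sequence = NULL, ptp_range = NULL) {
  cds <- toupper(as.character(cds))
  if (!grepl("^[ACGT]+$", cds)) {
    stop("cds must contain only A, C, G, T")
  }
  if (nchar(cds) %% 3L != 0L) {
    stop("cds length must be a multiple of 3")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  if (grepl("\\*", aa)) {
    stop("cds must not contain stop codons")
  }
  if (!is.null(aa_sequence)) {
    aa_sequence <- toupper(as.character(aa_sequence))
    if (!identical(aa_sequence, aa)) {
      stop("cds does not translate to the supplied aa_sequence")
    }
  }
  if (!all(strsplit(aa, "")[[1]] %in% aa_alphabet())) {
    stop("reference protein contains a non-standard residue letter")
  }
  L <- nchar(aa)
  windows <- list(FL = c(1L, L))
  if (!is.null(ptp_range)) {
    ptp_range <- as.integer(ptp_range)
    if (length(ptp_range) != 2L || ptp_range[1] < 1L || ptp_range[2] > L ||
        ptp_range[1] > ptp_range[2]) {
      stop("ptp_range must be an increasing interval within 1..", L)
    }
    windows$PTP <- ptp_range
  }
  structure(list(name = name, aa = aa, cds = cds, windows = windows),
            class = "protein_reference")
}

#' @export
print.protein_reference <- function(x, ...) {
  cat("protein_reference:", x$name, "\n")
  cat("  length:", nchar(x$aa), "residues\n")
  for (w in names(x$windows)) {
    cat(sprintf("  window %s: %d..%d\n", w, x$windows[[w]][1], x$windows[[w]][2]))
  }
  invisible(x)
}

#' Residue window of a construct
#'
#' @param ref A [protein_reference()].
#' @param construct `"FL"` or `"PTP"`.
#' @return Inclusive 1-based `c(start, end)` residue interval.
#' @export
construct_range <- function(ref, construct = c("FL", "PTP")) {
  construct <- match.arg(construct)
  w <- ref$windows[[construct]]
  if (is.null(w)) stop("reference has no ", construct, " window defined")
  w
}

#' Enumerate the single-substitution variant space of a construct
#'
#' Every position in the construct window crossed with every non-wild-type
#' substitution: 19 substitutions per position, 20 when stops are
#' included. Order is deterministic: position ascending, then the fixed
#' amino-acid order of [aa_alphabet()].
#'
#' @param ref A [protein_reference()].
#' @param construct `"FL"` or `"PTP"`.
#' @param include_stop Enumerate nonsense (`*`) variants too?
#' @return data.frame with columns `construct`, `position`, `wt_aa`,
#'   `mut_aa`, `variant_id` (e.g. `"E76K"`). Positions are global,
#'   full-length residue numbers even for the PTP window, matching
#'   mutation names such as E76K.
#' @export
enumerate_variants <- function(ref, construct = c("FL", "PTP"),
                               include_stop = FALSE) {
  construct <- match.arg(construct)
  rng <- construct_range(ref, construct)
  positions <- seq.int(rng[1], rng[2])
  wt <- strsplit(substr(ref$aa, rng[1], rng[2]), "")[[1]]
  subs <- aa_alphabet(include_stop)
  n_sub <- length(subs) - 1L
  pos_rep <- rep(positions, each = n_sub)
  wt_rep <- rep(wt, each = n_sub)
  mut <- unlist(lapply(wt, function(a) subs[subs != a]), use.names = FALSE)
  data.frame(
    construct = construct,
    position = pos_rep,
    wt_aa = wt_rep,
    mut_aa = mut,
    variant_id = paste0(wt_rep, pos_rep, mut),
    stringsAsFactors = FALSE
  )
}

#' Amino acids reachable from a codon by one nucleotide substitution
#'
#' Translates all nine single-nucleotide neighbors of a codon under the
#' standard genetic code and returns the resulting amino acids (including
#' `*`), excluding the codon's own amino acid. This is the genetic
#' accessibility used to ask which missense changes are one mutation away
#' from the wild-type gene.
#'
#' @param codon 3-letter A/C/G/T string.
#' @return Character vector of accessible amino acids in [aa_alphabet()]
#'   order with `*` last; at most 9 elements.
#' @export
single_nt_accessible <- function(codon) {
  codon <- toupper(as.character(codon))
  if (nchar(codon) != 3L || !grepl("^[ACGT]{3}$", codon)) {
    stop("codon must be a 3-letter A/C/G/T string")
  }
  bases <- c("A", "C", "G", "T")
  nt <- strsplit(codon, "")[[1]]
  neighbors <- character(0)
  for (i in 1:3) {
    for (b in bases[bases != nt[i]]) {
      alt <- nt
      alt[i] <- b
      neighbors <- c(neighbors, paste(alt, collapse = ""))
    }
  }
  aas <- unname(Biostrings::GENETIC_CODE[neighbors])
  self <- unname(Biostrings::GENETIC_CODE[[codon]])
  acc <- setdiff(unique(aas), self)
  order_ref <- aa_alphabet(include_stop = TRUE)
  acc[order(match(acc, order_ref))]
}

#' Flag variants reachable by a single nucleotide substitution
#'
#' For each variant, looks up the wild-type codon at its position in the
#' reference CDS and asks whether the mutant amino acid is in that codon's
#' [single_nt_accessible()] set.
#'
#' @param variants data.frame as produced by [enumerate_variants()].
#' @param ref A [protein_reference()] whose CDS covers all positions.
#' @return `variants` with an added logical column `accessible`.
#' @export
annotate_accessibility <- function(variants, ref) {
  L <- nchar(ref$aa)
  if (any(variants$position < 1L | variants$position > L)) {
    stop("variant position outside the reference CDS")
  }
  codons <- substring(ref$cds, 3L * variants$position - 2L, 3L * variants$position)
  acc_sets <- lapply(unique(codons), single_nt_accessible)
  names(acc_sets) <- unique(codons)
  variants$accessible <- mapply(
    function(codon, mut) mut %in% acc_sets[[codon]],
    codons, variants$mut_aa, USE.NAMES = FALSE
  )
  variants
}

#' Read a protein/CDS reference from FASTA files
#'
#' @param protein_fasta Path to a single-record protein FASTA, or `NULL`
#'   to derive the protein from the CDS.
#' @param cds_fasta Path to a single-record nucleotide FASTA.
#' @param name Reference name; defaults to the CDS record name.
#' @param ptp_range Optional PTP window, passed to [protein_reference()].
#' @return A [protein_reference()].
#' @export
read_reference_fasta <- function(cds_fasta, protein_fasta = NULL, name = NULL,
                                 ptp_range = NULL) {
  cds_set <- Biostrings::readDNAStringSet(cds_fasta)
  if (length(cds_set) != 1L) stop("cds_fasta must contain exactly one record")
  aa <- NULL
  if (!is.null(protein_fasta)) {
    aa_set <- Biostrings::readAAStringSet(protein_fasta)
    if (length(aa_set) != 1L) stop("protein_fasta must contain exactly one record")
    aa <- as.character(aa_set[[1]])
  }
  protein_reference(
    name = if (is.null(name)) names(cds_set)[1] else name,
    cds = as.character(cds_set[[1]]),
    aa_sequence = aa,
    ptp_range = ptp_range
  )
}

#' Write a reference to FASTA files
#'
#' @param ref A [protein_reference()].
#' @param cds_fasta,protein_fasta Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_reference_fasta <- function(ref, cds_fasta = NULL, protein_fasta = NULL) {
  if (!is.null(cds_fasta)) {
    x <- Biostrings::DNAStringSet(ref$cds)
    names(x) <- ref$name
    Biostrings::writeXStringSet(x, cds_fasta)
  }
  if (!is.null(protein_fasta)) {
    x <- Biostrings::AAStringSet(ref$aa)
    names(x) <- ref$name
    Biostrings::writeXStringSet(x, protein_fasta)
  }
  invisible(c(cds_fasta, protein_fasta))
}

#' Serialize / read a variant table as TSV
#'
#' Columns: `construct`, `position`, `wt_aa`, `mut_aa`, `variant_id`
#' (plus any extra columns present).
#'
#' @param variants Variant data.frame.
#' @param path Output path.
#' @return `write_variant_table`: the path, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

## Parse "E76K"-style ids into (wt, pos, mut); vectorized.
parse_variant_id <- function(ids) {
  m <- regmatches(ids, regexec("^([A-Z])([0-9]+)([A-Z*])$", ids))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed variant_id: ", paste(ids[bad], collapse = ", "))
  data.frame(
    wt_aa = vapply(m, `[`, character(1), 2L),
    position = as.integer(vapply(m, `[`, character(1), 3L)),
    mut_aa = vapply(m, `[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
}
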