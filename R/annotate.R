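# From raw evidence to phyletic profiles and per-genome binding-site
# sequences: homology-hit thresholds, promoter-window extraction,
# mapping of reference site coordinates through a gapped MSA, clade
# consensus sequences, and merging of near-identical interactions.
#
# Coordinates are 0-based half-open everywhere inside the package;
# all TSV input/output uses 1-based inclusive coordinates (documented
# in the file headers written by the pipeline).

#' Normalize an E-value to a reference search-space size
#'
#' E-values scale linearly with the size of the searched database, so a
#' hit in a small genome is rescaled to the value it would attain in a
#' reference-sized genome (default 4e6 bases), making presence calls
#' comparable across genomes.
#'
#' @param e_raw Reported E-value(s), non-negative.
#' @param genome_length Searched genome length(s) in bases, positive.
#' @param reference_size Reference genome size in bases (default `4e6`).
#' @return Normalized E-value(s).
#' @export
normalize_evalue <- function(e_raw, genome_length, reference_size = 4e6) {
  if (any(!is.finite(genome_length)) || any(genome_length <= 0)) {
    stop("genome length must be positive")
  }
  if (any(e_raw < 0)) stop("E-value must be non-negative")
  e_raw * reference_size / genome_length
}

#' Call trait presence per genome from homology hits
#'
#' A trait (e.g. an ncRNA family) is present in a genome iff at least
#' one hit from any family member has normalized E-value `<= e_max` and
#' identity `>= id_min` (both thresholds inclusive).  Genomes with no
#' hits are absent.
#'
#' @param hits Data frame with columns `genome`, `evalue` (already
#'   normalized, see [normalize_evalue()]), and `identity` (fraction in
#'   \[0, 1\]).
#' @param genomes Character vector of all genome labels to report.
#' @param e_max Maximum E-value (default 10).
#' @param id_min Minimum identity fraction (default 0.30).
#' @return Named 0/1 integer vector over `genomes` (a phyletic profile).
#' @export
call_presence_from_hits <- function(hits, genomes, e_max = 10, id_min = 0.30) {
  stopifnot(all(c("genome", "evalue", "identity") %in% names(hits)))
  if (any(hits$identity < 0 | hits$identity > 1, na.rm = TRUE)) {
    stop("identity must be a fraction in [0, 1]")
  }
  keep <- hits$evalue <= e_max & hits$identity >= id_min
  present <- unique(hits$genome[keep])
  out <- as.integer(genomes %in% present)
  names(out) <- genomes
  out
}

#' Extract the translation-start window of a gene
#'
#' Returns the sequence from `upstream` nt before to `downstream` nt
#' after the first base of the start codon (default -150..+50, a
#' 0-based half-open window of length `upstream + downstream`).  On the
#' reverse strand the window is taken in gene orientation, i.e. the
#' reverse complement of the mirrored forward-coordinate window.  The
#' window is truncated (never padded) at contig boundaries and a
#' message is emitted when truncation occurs.
#'
#' @param genome_seq Contig sequence (character scalar, DNA or RNA).
#' @param cds_start 0-based position of the first base of the start
#'   codon in forward-strand coordinates.
#' @param strand `"+"` or `"-"`.
#' @param upstream,downstream Window extent in nt (defaults 150 and 50).
#' @return The window sequence in gene orientation (character scalar).
#' @export
extract_window <- function(genome_seq, cds_start, strand = c("+", "-"),
                           upstream = 150L, downstream = 50L) {
  strand <- match.arg(strand)
  len <- nchar(genome_seq)
  if (cds_start < 0 || cds_start >= len) {
    stop("cds_start outside the contig (0 <= cds_start < ", len, ")")
  }
  if (strand == "+") {
    lo <- cds_start - upstream
    hi <- cds_start + downstream
  } else {
    lo <- cds_start + 1L - downstream
    hi <- cds_start + 1L + upstream
  }
  clo <- max(0L, lo)
  chi <- min(len, hi)
  if (clo > lo || chi < hi) {
    message("window truncated at contig boundary (requested [", lo, ", ", hi,
            "), clipped to [", clo, ", ", chi, "))")
  }
  out <- substr(genome_seq, clo + 1L, chi)
  if (strand == "-") out <- revcomp(out)
  out
}

#' Reverse complement (DNA or RNA)
#'
#' Complements A/C/G/T/U (case preserved, `N` fixed) and reverses.
#' `U` maps to `A` and `A` maps to `T` for DNA input or `U` for RNA
#' input (input containing `U` is treated as RNA).
#'
#' @param x Character vector of sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    rna <- grepl("[Uu]", s)
    comp <- if (rna) chartr("ACGUacguTt", "UGCAugcaAa", s)
            else chartr("ACGTacgt", "TGCAtgca", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Map reference site coordinates through a gapped alignment
#'
#' Pads the site by `pad` nt on each side in ungapped reference
#' coordinates (clipped at the sequence ends), maps the padded site to
#' alignment columns via the reference row (columns where the reference
#' carries a gap are retained, since other rows may hold bases there),
#' and returns, per row, the ungapped subsequence over those columns
#' together with a gap flag computed over the unpadded core columns
#' only.  A gap anywhere in the core columns of a row marks that row as
#' lacking the site; gaps confined to the pads do not.
#'
#' @param msa Named character vector of equal-width aligned sequences
#'   (or a `Biostrings` `XStringSet`).
#' @param ref_row Name of the reference row.
#' @param site_start,site_end 0-based half-open site interval in
#'   ungapped reference coordinates.
#' @param pad Pad width in nt (default 5).
#' @return Data frame with columns `genome`, `seq` (ungapped padded
#'   extraction), `core_seq` (ungapped core-only extraction), and
#'   `gap_flag` (logical).
#' @export
map_site_columns <- function(msa, ref_row, site_start, site_end, pad = 5L) {
  msa <- .as_aligned_character(msa)
  if (!ref_row %in% names(msa)) stop("reference row '", ref_row, "' not in MSA")
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) stop("alignment rows differ in width")
  ref_chars <- strsplit(msa[[ref_row]], "", fixed = TRUE)[[1]]
  cols_of <- which(ref_chars != "-")
  ulen <- length(cols_of)
  if (!(site_start >= 0 && site_start < site_end && site_end <= ulen)) {
    stop("site interval outside the ungapped reference length (", ulen, ")")
  }
  p_start <- max(0L, site_start - pad)
  p_end <- min(ulen, site_end + pad)
  core_cols <- seq(cols_of[site_start + 1L], cols_of[site_end])
  pad_cols <- seq(cols_of[p_start + 1L], cols_of[p_end])
  rows <- lapply(names(msa), function(g) {
    chars <- strsplit(msa[[g]], "", fixed = TRUE)[[1]]
    core <- chars[core_cols]
    sub <- chars[pad_cols]
    data.frame(genome = g,
               seq = paste(sub[sub != "-"], collapse = ""),
               core_seq = paste(core[core != "-"], collapse = ""),
               gap_flag = any(core == "-"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Majority-rule consensus of aligned rows
#'
#' Column-wise majority over the given rows; gap characters do not
#' vote and all-gap columns are dropped.  Ties are broken alphabetically
#' (A < C < G < T < U) and reported via a message.  Used as the
#' ancestral-sequence stand-in when a clade's common-ancestor sequence
#' is needed.
#'
#' @param rows Character vector of equal-width aligned sequences.
#' @return Consensus sequence (ungapped character scalar).
#' @export
consensus_site <- function(rows) {
  if (length(rows) == 0) stop("consensus of an empty row set")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("rows differ in width")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  ties <- 0L
  cons <- apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(NA_character_)
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      ties <<- ties + 1L
      top <- sort(top)[1L]
    }
    top[1L]
  })
  if (ties > 0) message(ties, " consensus tie(s) broken alphabetically")
  paste(cons[!is.na(cons)], collapse = "")
}

#' Merge near-identical interactions of one sRNA-target pair
#'
#' Two records of the same (sRNA, target) pair describe the same
#' interaction when their binding sites are closer than `min_dist` nt
#' on the sRNA *and* on the mRNA; records at or beyond `min_dist` on
#' either molecule stay distinct.  Merging is a transitive closure and
#' the merged record spans the union of the member intervals.  The
#' distance is measured edge-to-edge between intervals by default
#' (overlap counts as 0); `anchor = "start"` uses start-to-start
#' distance instead.
#'
#' @param records Data frame with columns `srna`, `target`,
#'   `sbs_start`, `sbs_end`, `mbs_start`, `mbs_end` (0-based half-open).
#'   Additional columns are carried over from the first member of each
#'   merged group.
#' @param min_dist Distance (nt) at which records stay distinct
#'   (default 10).
#' @param anchor `"edge"` (default) or `"start"`.
#' @return Data frame of merged records, plus a `n_merged` column.
#' @export
distinct_interactions <- function(records, min_dist = 10L,
                                  anchor = c("edge", "start")) {
  anchor <- match.arg(anchor)
  need <- c("srna", "target", "sbs_start", "sbs_end", "mbs_start", "mbs_end")
  stopifnot(all(need %in% names(records)))
  if (nrow(records) == 0) {
    records$n_merged <- integer(0)
    return(records)
  }
  dist1 <- function(s1, e1, s2, e2) {
    if (anchor == "start") return(abs(s1 - s2))
    max(0L, max(s1, s2) - min(e1, e2))
  }
  key <- paste(records$srna, records$target, sep = "\r")
  out <- lapply(split(seq_len(nrow(records)), key), function(ii) {
    n <- length(ii)
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a >= b) next
      ra <- records[ii[a], ]; rb <- records[ii[b], ]
      ds <- dist1(ra$sbs_start, ra$sbs_end, rb$sbs_start, rb$sbs_end)
      dm <- dist1(ra$mbs_start, ra$mbs_end, rb$mbs_start, rb$mbs_end)
      if (ds < min_dist && dm < min_dist) parent[find(a)] <- find(b)
    }
    comp <- vapply(seq_len(n), find, integer(1))
    do.call(rbind, lapply(unique(comp), function(cid) {
      grp <- records[ii[comp == cid], , drop = FALSE]
      merged <- grp[1L, , drop = FALSE]
      merged$sbs_start <- min(grp$sbs_start); merged$sbs_end <- max(grp$sbs_end)
      merged$mbs_start <- min(grp$mbs_start); merged$mbs_end <- max(grp$mbs_end)
      merged$n_merged <- nrow(grp)
      merged
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## ---- internal ---------------------------------------------------------

.as_aligned_character <- function(msa) {
  if (inherits(msa, "XStringSet")) {
    out <- as.character(msa)
  } else {
    out <- msa
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("alignment rows must be named")
  }
  out
}

#' Read a gapped FASTA alignment
#'
#' @param path FASTA file path.
#' @return Named character vector of aligned rows.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a gapped FASTA alignment
#'
#' @param msa Named character vector of aligned rows.
#' @param path Output FASTA path.
#' @export
write_alignment <- function(msa, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(msa), path)
  invisible(path)
}
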