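# Taxon assignment for short MT-CYB amplicons against a labelled haplotype
# panel: primer trimming with mismatch tolerance, then Hamming-distance
# classification on the equal-length insert. Indels are not expected in the
# conserved 110-bp fragment, so no gapped alignment is attempted.

#' Default MT-CYB amplification primers
#'
#' The caprine cytochrome-b primer pair CapFC1/CapRB1b used to amplify the
#' 110-bp diagnostic fragment.
#'
#' @return A list with `forward` and `reverse` primer strings (5' to 3').
#' @export
default_primers <- function() {
  list(forward = "CTCTGTAACTCACATTTGTC",
       reverse = "GTTTCATGTTTCTAGAAAGGT")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# First match position of `pattern` in `subject` with at most `max_mismatch`
# substitutions, or NA.
find_primer <- function(pattern, subject, max_mismatch) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  if (length(m) == 0) return(NA_integer_)
  Biostrings::start(m)[1]
}

#' Trim amplification primers from a read
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer, each allowing up to `max_mismatch` substitutions, and returns
#' the enclosed insert. Both read orientations are tried before failing.
#'
#' @param read sequence string.
#' @param forward,reverse primer strings (5' to 3'), defaulting to the
#'   MT-CYB pair of [default_primers()].
#' @param max_mismatch substitutions tolerated per primer (default 1).
#' @return The insert sequence (character scalar).
#' @export
trim_primers <- function(read, forward = default_primers()$forward,
                         reverse = default_primers()$reverse,
                         max_mismatch = 1) {
  stopifnot(is.character(read), length(read) == 1L,
            nchar(read) > nchar(forward) + nchar(reverse))
  rc_rev <- revcomp(reverse)
  for (candidate in c(read, revcomp(read))) {
    f_at <- find_primer(forward, candidate, max_mismatch)
    if (is.na(f_at)) next
    insert_start <- f_at + nchar(forward)
    tail_seq <- substr(candidate, insert_start, nchar(candidate))
    r_at <- find_primer(rc_rev, tail_seq, max_mismatch)
    if (is.na(r_at)) next
    return(substr(tail_seq, 1, r_at - 1))
  }
  stop("primer_not_found")
}

# Hamming distance with N in the query treated as mismatch-neutral
# (conservative for degraded aDNA); sequences must have equal length.
hamming_n_neutral <- function(query, reference) {
  q <- strsplit(toupper(query), "")[[1]]
  r <- strsplit(toupper(reference), "")[[1]]
  stopifnot(length(q) == length(r))
  sum(q != r & q != "N")
}

#' Assign a taxon to a trimmed MT-CYB fragment
#'
#' Computes the Hamming distance from the query to every panel entry
#' (N bases in the query are mismatch-neutral) and reports the
#' minimal-distance taxon, the mismatch count, and the margin to the best
#' entry of any other taxon. Equal minimal distance across distinct taxa
#' is flagged ambiguous. The result is invariant under panel row order.
#'
#' @param query trimmed insert sequence; must match the panel fragment
#'   length.
#' @param panel a `haplotype_panel` (columns id, taxon, status, sequence).
#' @param query_id identifier copied into the result.
#' @return An `assignment_result` data frame row: query_id, taxon, status,
#'   mismatches, margin, identical, ambiguous.
#' @export
assign_taxon <- function(query, panel, query_id = "query") {
  stopifnot(inherits(panel, "haplotype_panel"), nrow(panel) >= 1,
            is.character(query), length(query) == 1L)
  lens <- unique(nchar(panel$sequence))
  if (length(lens) != 1L) stop("panel sequences have unequal lengths")
  if (nchar(query) != lens) {
    stop("length_mismatch: query ", nchar(query), " bp vs panel ", lens, " bp")
  }
  d <- vapply(panel$sequence, function(s) hamming_n_neutral(query, s),
              numeric(1))
  # per-taxon minimal distance; ties within a taxon are not ambiguous
  taxa <- sort(unique(panel$taxon))
  d_taxon <- vapply(taxa, function(tx) min(d[panel$taxon == tx]), numeric(1))
  ord <- order(d_taxon, taxa)  # taxon name breaks exact ties deterministically
  best_tx <- taxa[ord[1]]
  best_d <- d_taxon[ord[1]]
  margin <- if (length(taxa) > 1) d_taxon[ord[2]] - best_d else Inf
  best_rows <- which(panel$taxon == best_tx)
  best_row <- best_rows[which.min(d[best_rows])]
  res <- data.frame(
    query_id = query_id,
    taxon = best_tx,
    status = panel$status[best_row],
    mismatches = best_d,
    margin = margin,
    identical = best_d == 0,
    ambiguous = is.finite(margin) && margin == 0)
  class(res) <- c("assignment_result", "data.frame")
  res
}

#' Trim and classify a set of reads
#'
#' Applies [trim_primers()] then [assign_taxon()] to each read; reads whose
#' primers cannot be located are reported with `NA` taxon and reason
#' `primer_not_found`.
#'
#' @param reads data frame with columns `read_id` and `sequence`.
#' @param panel a `haplotype_panel`.
#' @param primers list with `forward`/`reverse` strings.
#' @param max_mismatch substitutions tolerated per primer.
#' @return Data frame with one row per read: query_id, taxon, status,
#'   mismatches, margin, identical, ambiguous.
#' @export
classify_reads <- function(reads, panel, primers = default_primers(),
                           max_mismatch = 1) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence") %in% names(reads)))
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    insert <- tryCatch(
      trim_primers(reads$sequence[i], primers$forward, primers$reverse,
                   max_mismatch),
      error = function(e) NA_character_)
    if (is.na(insert)) {
      return(data.frame(query_id = reads$read_id[i], taxon = NA_character_,
                        status = NA_character_, mismatches = NA_real_,
                        margin = NA_real_, identical = NA,
                        ambiguous = NA))
    }
    assign_taxon(insert, panel, query_id = reads$read_id[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a labelled haplotype panel from FASTA
#'
#' Panel FASTA headers carry `taxon=` and `status=` tags, e.g.
#' `>hap01 taxon=Ovis_aries status=domestic`; underscores in taxon names
#' are converted to spaces.
#'
#' @param path FASTA file path.
#' @return A `haplotype_panel` data frame.
#' @export
read_haplotype_panel <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  tag <- function(h, key) {
    m <- regmatches(h, regexpr(paste0(key, "=\\S+"), h))
    if (!length(m)) return(NA_character_)
    gsub("_", " ", sub(paste0(key, "="), "", m))
  }
  panel <- data.frame(
    id = vapply(strsplit(headers, "\\s+"), `[`, character(1), 1),
    taxon = vapply(headers, tag, character(1), key = "taxon",
                   USE.NAMES = FALSE),
    status = vapply(headers, tag, character(1), key = "status",
                    USE.NAMES = FALSE),
    sequence = as.character(seqs))
  if (anyNA(panel$taxon) || anyNA(panel$status)) {
    stop("panel headers must carry taxon= and status= tags")
  }
  rownames(panel) <- NULL
  class(panel) <- c("haplotype_panel", "data.frame")
  panel
}

#' Write a haplotype panel or read set to FASTA
#'
#' @param x a `haplotype_panel`, or a data frame with `read_id` and
#'   `sequence` columns.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta_table <- function(x, path) {
  if (inherits(x, "haplotype_panel")) {
    headers <- sprintf("%s taxon=%s status=%s", x$id,
                       gsub(" ", "_", x$taxon), x$status)
    seqs <- x$sequence
  } else {
    stopifnot(all(c("read_id", "sequence") %in% names(x)))
    headers <- x$read_id
    seqs <- x$sequence
  }
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
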