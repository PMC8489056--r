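#' Find open reading frames
#'
#' Scans both strands of a nucleotide sequence for ATG-initiated,
#' stop-terminated open reading frames of at least \code{min_aa} residues,
#' under the standard genetic code. Coordinates are 0-based half-open on the
#' forward strand and include the stop codon, so a complete CDS of L
#' nucleotides encodes L/3 - 1 amino acids. Codons containing N are
#' untranslatable and split any ORF that would span them.
#'
#' @param seq Nucleotide sequence (character scalar over A, C, G, T, N;
#'   case-insensitive) or a \code{Biostrings::DNAString}.
#' @param min_aa Minimum protein length in residues (>= 1).
#' @param sequence_id Identifier carried into the result.
#' @return Data frame sorted by protein length (descending) with columns
#'   \code{sequence_id}, \code{start}, \code{end}, \code{strand},
#'   \code{frame}, \code{protein}.
#' @export
find_orfs <- function(seq, min_aa = 1, sequence_id = "seq1") {
  seq <- toupper(as.character(seq))
  if (!grepl("^[ACGTN]*$", seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  if (min_aa < 1) stop("min_aa must be >= 1")
  L <- nchar(seq)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else reverse_complement(seq)
    for (frame in 0:2) {
      n_codons <- (nchar(s) - frame) %/% 3
      if (n_codons < 2) next
      codons <- substring(s, frame + 1 + 3 * (seq_len(n_codons) - 1),
                          frame + 3 * seq_len(n_codons))
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      has_n <- grepl("N", codons, fixed = TRUE)
      open_at <- NA_integer_
      for (i in seq_len(n_codons)) {
        if (has_n[i]) { open_at <- NA_integer_; next }   # ORFs cannot span N
        if (is_stop[i]) {
          if (!is.na(open_at)) {
            aa_len <- i - open_at
            if (aa_len >= min_aa) {
              # coordinates on the scanned strand, then mapped to forward
              a <- frame + 3 * (open_at - 1)      # 0-based start
              b <- frame + 3 * i                  # half-open end incl. stop
              if (strand == "-") { tmp <- a; a <- L - b; b <- L - tmp }
              hits[[length(hits) + 1]] <- data.frame(
                sequence_id = sequence_id, start = a, end = b,
                strand = strand, frame = frame,
                protein = translate_cds(paste(codons[open_at:(i - 1)],
                                              collapse = "")),
                stringsAsFactors = FALSE)
            }
            open_at <- NA_integer_
          }
        } else if (is.na(open_at) && codons[i] == "ATG") {
          open_at <- i
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(-nchar(out$protein), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate a coding sequence
#'
#' Standard genetic code; a trailing stop codon, if present, is dropped from
#' the protein.
#'
#' @param cds Nucleotide sequence whose length is a multiple of 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) stop("CDS length must be a multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Nucleotide character scalar (A, C, G, T, N).
#' @return Reverse-complemented character scalar.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(as.character(seq)))))
}

#' Scan a protein for a degenerate motif
#'
#' Matches a motif over the 20 amino-acid letters plus X (any residue)
#' against a protein, reporting every — possibly overlapping — match start.
#' TGXXGF (NADPH-binding) and YXXXK (active site) are the classic fatty
#' acyl-CoA reductase motifs this was built for.
#'
#' @param protein Amino-acid string.
#' @param motif Degenerate pattern, e.g. \code{"TGXXGF"}.
#' @param zero_based Return 0-based positions (default); \code{FALSE} gives
#'   1-based positions for human-readable reports.
#' @return Integer vector of match start positions.
#' @export
motif_scan <- function(protein, motif, zero_based = TRUE) {
  protein <- toupper(as.character(protein))
  motif <- toupper(as.character(motif))
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", motif)) {
    stop("motif must use the 20 amino-acid letters plus X")
  }
  pattern <- paste0("(?=", gsub("X", ".", motif, fixed = TRUE), ")")
  hit <- gregexpr(pattern, protein, perl = TRUE)[[1]]
  if (hit[1] == -1) return(integer(0))
  as.integer(hit) - if (zero_based) 1L else 0L
}

#' Find ORFs and scan motifs across a FASTA file
#'
#' @param fasta_path FASTA file of nucleotide sequences.
#' @param min_aa Minimum ORF length in residues.
#' @param motifs Character vector of degenerate motifs to scan in each ORF's
#'   protein.
#' @return Data frame of ORF hits (see \code{\link{find_orfs}}) with one
#'   additional column per motif holding comma-separated 1-based positions.
#' @export
orf_report <- function(fasta_path, min_aa = 100,
                       motifs = c("TGXXGF", "YXXXK")) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  res <- lapply(seq_along(seqs), function(i) {
    find_orfs(as.character(seqs[[i]]), min_aa = min_aa,
              sequence_id = names(seqs)[i])
  })
  out <- do.call(rbind, res)
  for (mf in motifs) {
    out[[mf]] <- vapply(out$protein, function(p) {
      paste(motif_scan(p, mf, zero_based = FALSE), collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  }
  rownames(out) <- NULL
  out
}
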