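#' @importFrom utils read.delim write.table
#' @importFrom stats setNames
NULL

# Alphabets. Amino-acid alphabet is the 20 standard residues plus X (unknown);
# nucleotide alphabet is ACGT plus N. Residues are case-normalized to upper.
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X")
NT_ALPHABET <- c("A","C","G","T","N")

#' Construct a sequence collection
#'
#' A `seq_set` is the package's lightweight sequence container: a named
#' character vector of residue strings (names are identifiers, unique, no
#' whitespace) with a declared alphabet and an optional description per
#' record. Residues are upper-cased on construction and validated against
#' the declared alphabet.
#'
#' @param residues character vector of sequences.
#' @param ids character vector of unique identifier tokens (no whitespace).
#' @param alphabet `"aa"` (amino acid, 20 letters + X) or `"nt"` (ACGTN).
#' @param descriptions optional character vector of free-text descriptions.
#' @return a `seq_set` object.
#' @export
seq_set <- function(residues, ids = NULL, alphabet = c("aa", "nt"),
                    descriptions = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(ids)) ids <- names(residues)
  residues <- toupper(as.character(residues))
  if (length(residues) > 0L) {
    if (is.null(ids)) stop("sequence ids are required")
    ids <- as.character(ids)
    if (anyNA(ids) || any(ids == "") || any(grepl("\\s", ids)))
      stop("sequence ids must be non-empty whitespace-free tokens")
    dup <- ids[duplicated(ids)]
    if (length(dup) > 0L)
      stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
    if (any(!nzchar(residues)))
      stop("empty sequence(s): ", paste(ids[!nzchar(residues)], collapse = ", "))
    ok_chars <- alphabet_chars(alphabet)
    for (i in seq_along(residues)) {
      ch <- strsplit(residues[[i]], "", fixed = TRUE)[[1L]]
      bad <- which(!(ch %in% ok_chars))
      if (length(bad) > 0L)
        stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                     ch[bad[1L]], bad[1L], ids[i]))
    }
    names(residues) <- ids
  }
  if (is.null(descriptions)) descriptions <- rep("", length(residues))
  structure(residues, class = "seq_set", alphabet = alphabet,
            descriptions = as.character(descriptions))
}

alphabet_chars <- function(alphabet) {
  if (alphabet == "aa") AA_ALPHABET else NT_ALPHABET
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set of %d %s sequence(s)\n", length(x),
              if (attr(x, "alphabet") == "aa") "amino-acid" else "nucleotide"))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %s [%d] %s%s\n", names(x)[i], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Read a FASTA file into a seq_set
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; this wrapper adds
#' identifier and alphabet validation: one record per header, wrapped lines
#' concatenated, residues upper-cased, record order preserved. The record id
#' is the first whitespace-delimited token of the header; the remainder is
#' kept as the description.
#'
#' @param path FASTA file path. An empty file yields an empty collection.
#' @param alphabet `"aa"` or `"nt"`.
#' @return a [seq_set].
#' @export
read_fasta <- function(path, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(seq_set(character(0), character(0), alphabet))
  bs <- Biostrings::readBStringSet(path)
  headers <- names(bs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_set(as.character(bs), ids, alphabet, descriptions = desc)
}

#' Write a seq_set to FASTA (wrapped at 60 columns)
#'
#' @param x a [seq_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  desc <- attr(x, "descriptions")
  headers <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  bs <- Biostrings::BStringSet(setNames(unclass(x), headers))
  Biostrings::writeXStringSet(bs, filepath = path, width = 60L)
  invisible(path)
}

#' Translate the longest open reading frame of a transcript
#'
#' Scans reading frames for open reading frames (ATG through the first
#' in-frame stop, stop excluded) and translates the longest one with the
#' standard genetic code. Ties are broken by lowest frame index, then
#' smallest start coordinate. Coordinates are 0-based half-open on the
#' input strand.
#'
#' @param residues a nucleotide sequence string (ACGTN), length >= 3.
#' @param id identifier for the resulting protein record.
#' @param frames `"forward3"` (default; strand-oriented mRNA) or `"all6"`.
#' @param min_orf_aa minimum ORF length in amino acids (default 30);
#'   shorter ORFs yield a no-ORF result.
#' @return a list with `protein` (string or `NA` if no qualifying ORF),
#'   `frame` (0..2, negative strand frames 3..5), `start`, `end`
#'   (0-based half-open nucleotide coordinates of the ORF, stop excluded),
#'   and `found` (logical).
#' @export
longest_orf_protein <- function(residues, id = "orf", frames = c("forward3", "all6"),
                                min_orf_aa = 30L) {
  frames <- match.arg(frames)
  residues <- toupper(residues)
  ch <- strsplit(residues, "", fixed = TRUE)[[1L]]
  if (any(!(ch %in% NT_ALPHABET)))
    stop("non-nucleotide character in transcript: ",
         ch[which(!(ch %in% NT_ALPHABET))[1L]])
  if (nchar(residues) < 3L) stop("transcript shorter than one codon")
  strands <- list(list(seq = residues, offset = 0L))
  if (frames == "all6")
    strands <- c(strands, list(list(seq = revcomp(residues), offset = 3L)))
  best <- NULL
  for (st in strands) {
    for (f in 0:2) {
      orfs <- scan_frame_orfs(st$seq, f)
      for (o in orfs) {
        if (o$aa_len < min_orf_aa) next
        if (is.null(best) ||
            o$aa_len > best$aa_len ||
            (o$aa_len == best$aa_len &&
             (f + st$offset < best$frame ||
              (f + st$offset == best$frame && o$start < best$start)))) {
          best <- o
          best$frame <- f + st$offset
        }
      }
    }
  }
  if (is.null(best))
    return(list(protein = NA_character_, frame = NA_integer_,
                start = NA_integer_, end = NA_integer_, found = FALSE))
  strand_seq <- if (best$frame < 3L) residues else revcomp(residues)
  prot <- translate_nt(substr(strand_seq, best$start + 1L, best$end))
  list(protein = prot, frame = best$frame, start = best$start, end = best$end,
       found = TRUE)
}

# All ORFs (ATG..stop, stop excluded) in one frame of one strand.
# Returns list of (start, end 0-based half-open, aa_len).
scan_frame_orfs <- function(s, frame) {
  n <- nchar(s)
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  if (length(starts) == 0L) return(list())
  codons <- substring(s, starts, starts + 2L)
  is_start <- codons == "ATG"
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  orfs <- list()
  open <- NA_integer_
  for (i in seq_along(codons)) {
    if (is.na(open) && is_start[i]) open <- i
    if (!is.na(open) && is_stop[i]) {
      orfs[[length(orfs) + 1L]] <- list(start = starts[open] - 1L,
                                        end = starts[i] - 1L,
                                        aa_len = i - open)
      open <- NA_integer_
    }
  }
  orfs
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# Standard-code translation via the Biostrings genetic code table.
translate_nt <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(ifelse(aa == "*", "", aa), collapse = "")
}

#' Load an identifier map
#'
#' An `id_map` resolves raw identifiers (protein accessions, aliases,
#' case variants) to canonical gene symbols so that transcriptomic and
#' proteomic layers can be intersected. Canonical symbols are
#' case-insensitively unique; an alias must resolve to exactly one
#' canonical symbol.
#'
#' @param canonical character vector of canonical gene symbols.
#' @param aliases named character vector mapping alias -> canonical symbol
#'   (may be empty).
#' @return an `id_map` object.
#' @export
id_map <- function(canonical, aliases = character(0)) {
  canonical <- as.character(canonical)
  if (anyDuplicated(tolower(canonical)))
    stop("canonical symbols must be case-insensitively unique")
  if (length(aliases) > 0L) {
    if (is.null(names(aliases))) stop("aliases must be a named vector")
    key <- tolower(names(aliases))
    split_tgt <- split(as.character(aliases), key)
    multi <- vapply(split_tgt, function(v) length(unique(v)) > 1L, logical(1))
    if (any(multi))
      stop("alias maps to multiple canonical symbols: ",
           paste(names(split_tgt)[multi], collapse = ", "))
    if (any(!(tolower(aliases) %in% tolower(canonical))))
      stop("alias target not among canonical symbols")
  }
  structure(list(canonical = canonical,
                 canonical_lc = tolower(canonical),
                 alias_lc = tolower(names(aliases)),
                 alias_target = as.character(aliases)),
            class = "id_map")
}

#' Read an identifier map from TSV
#'
#' Expects columns `raw_id`, `canonical`, `aliases` (comma-separated,
#' may be empty). Rows where `raw_id` equals `canonical` declare canonical
#' symbols; aliases are attached to their row's canonical symbol.
#'
#' @param path TSV path with header.
#' @return an [id_map].
#' @export
read_id_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("raw_id", "canonical")
  if (!all(need %in% names(df))) stop("id map TSV needs columns raw_id, canonical")
  canonical <- unique(df$canonical)
  al <- character(0)
  raw_alias <- df$raw_id[tolower(df$raw_id) != tolower(df$canonical)]
  al <- c(al, setNames(df$canonical[tolower(df$raw_id) != tolower(df$canonical)],
                       raw_alias))
  if ("aliases" %in% names(df)) {
    for (i in seq_len(nrow(df))) {
      if (is.na(df$aliases[i]) || !nzchar(df$aliases[i])) next
      a <- trimws(strsplit(df$aliases[i], ",", fixed = TRUE)[[1L]])
      al <- c(al, setNames(rep(df$canonical[i], length(a)), a))
    }
  }
  al <- al[!duplicated(tolower(names(al)))]
  id_map(canonical, al)
}

#' Normalize raw identifiers to canonical gene symbols
#'
#' Case-insensitive exact match against canonical symbols first, then
#' against aliases. Unmapped identifiers are returned as `NA` with the raw
#' value preserved in the result's names — never silently dropped. The
#' operation is idempotent: a canonical symbol normalizes to itself.
#'
#' @param raw character vector of raw identifiers.
#' @param map an [id_map].
#' @return character vector of canonical symbols (`NA` where unmapped),
#'   named by the raw input.
#' @export
normalize_id <- function(raw, map) {
  stopifnot(inherits(map, "id_map"))
  raw <- as.character(raw)
  lc <- tolower(raw)
  out <- map$canonical[match(lc, map$canonical_lc)]
  miss <- is.na(out)
  if (any(miss) && length(map$alias_lc) > 0L) {
    tgt <- map$alias_target[match(lc[miss], map$alias_lc)]
    # alias targets are themselves canonical; emit the canonical casing
    out[miss] <- map$canonical[match(tolower(tgt), map$canonical_lc)]
  }
  setNames(out, raw)
}

#' Read transcript-to-gene models from TSV
#'
#' @param path TSV with header columns `transcript_id`, `gene_id`.
#' @return data.frame with columns transcript_id, gene_id.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "gene_id") %in% names(df)))
    stop("gene model TSV needs columns transcript_id, gene_id")
  df[, c("transcript_id", "gene_id")]
}
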