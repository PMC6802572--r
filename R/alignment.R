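#' Nucleotide alphabet with IUPAC ambiguity codes
#'
#' The engine's default alphabet: states A, C, G, T plus the IUPAC
#' ambiguity codes, with `-`, `?` and `N` treated as fully missing.
#' @return a list with `states` (character vector of length S) and
#'   `ambiguity` (named list mapping each legal character to the set of
#'   compatible state indices).
#' @export
nucleotide_alphabet <- function() {
  amb <- list(
    A = 1L, C = 2L, G = 3L, T = 4L,
    R = c(1L, 3L), Y = c(2L, 4L), S = c(2L, 3L), W = c(1L, 4L),
    K = c(3L, 4L), M = c(1L, 2L),
    B = c(2L, 3L, 4L), D = c(1L, 3L, 4L), H = c(1L, 2L, 4L), V = c(1L, 2L, 3L),
    N = 1:4, `-` = 1:4, `?` = 1:4
  )
  list(states = c("A", "C", "G", "T"), ambiguity = amb)
}

#' Construct an alignment
#'
#' Validates taxon names and sequences: equal lengths, unique names, and
#' only characters legal for the alphabet. Input is case-insensitive and
#' `U` is mapped to `T`.
#' @param taxon_names character vector of unique names.
#' @param sequences character vector of equal-length sequence strings.
#' @param alphabet see [nucleotide_alphabet()].
#' @return an object of class `pw_alignment` with `taxon_names`,
#'   `sequences`, `site_count`, `alphabet`.
#' @export
alignment <- function(taxon_names, sequences, alphabet = nucleotide_alphabet()) {
  taxon_names <- as.character(taxon_names)
  sequences <- toupper(as.character(sequences))
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  if (length(taxon_names) != length(sequences))
    pw_stop("names and sequences differ in length")
  if (anyDuplicated(taxon_names))
    pw_stop("duplicate taxon name: ",
            taxon_names[duplicated(taxon_names)][1])
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    pw_stop("sequences are not aligned: taxon '",
            taxon_names[which(lens != lens[1])[1]],
            "' has a different length")
  legal <- names(alphabet$ambiguity)
  for (k in seq_along(sequences)) {
    ch <- strsplit(sequences[k], "")[[1]]
    bad <- which(!(ch %in% legal))
    if (length(bad))
      pw_stop("illegal character '", ch[bad[1]], "' for taxon '",
              taxon_names[k], "' at site ", bad[1])
  }
  structure(list(taxon_names = taxon_names, sequences = sequences,
                 site_count = lens[1], alphabet = alphabet),
            class = "pw_alignment")
}

#' @export
print.pw_alignment <- function(x, ...) {
  cat(sprintf("<pw_alignment: %d taxa, %d sites>\n",
              length(x$taxon_names), x$site_count))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA (multi-line records) or relaxed PHYLIP (header
#' `"ntax nsites"`, whitespace-delimited names, sequences may continue
#' across lines). Parsing is case-insensitive; `U` becomes `T`.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`.
#' @param alphabet see [nucleotide_alphabet()].
#' @return a `pw_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"),
                           alphabet = nucleotide_alphabet()) {
  format <- match.arg(format)
  if (!file.exists(path)) pw_stop("file not found: ", path)
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = "AA", set.attributes = FALSE)
    if (!length(recs)) pw_stop("no FASTA records in ", path)
    alignment(names(recs),
              vapply(recs, paste, character(1), collapse = ""),
              alphabet = alphabet)
  } else {
    toks <- scan(path, what = character(), quiet = TRUE)
    if (length(toks) < 2) pw_stop("PHYLIP header missing in ", path)
    ntax <- suppressWarnings(as.integer(toks[1]))
    nsit <- suppressWarnings(as.integer(toks[2]))
    if (is.na(ntax) || is.na(nsit))
      pw_stop("malformed PHYLIP header in ", path)
    toks <- toks[-(1:2)]
    nm <- character(ntax); sq <- character(ntax)
    i <- 1L
    for (k in seq_len(ntax)) {
      if (i > length(toks)) pw_stop("PHYLIP file truncated at taxon ", k)
      nm[k] <- toks[i]; i <- i + 1L
      acc <- ""
      while (nchar(acc) < nsit) {
        if (i > length(toks))
          pw_stop("sequence for taxon '", nm[k], "' is shorter than ",
                  nsit, " sites")
        acc <- paste0(acc, toks[i]); i <- i + 1L
      }
      if (nchar(acc) != nsit)
        pw_stop("sequence for taxon '", nm[k], "' does not match ",
                nsit, " sites")
      sq[k] <- acc
    }
    alignment(nm, sq, alphabet = alphabet)
  }
}

#' Write an alignment as FASTA
#' @param aln a `pw_alignment`.
#' @param path output file.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(aln$taxon_names))
    writeLines(c(paste0(">", aln$taxon_names[k]), aln$sequences[k]), con)
  invisible(path)
}

#' Encode a tip sequence for the engine
#'
#' Compact mode maps each unambiguous character to its 0-based state index
#' and any ambiguity or gap to the sentinel index `S` ("missing", which
#' contributes a factor of one to the likelihood). Partial mode maps each
#' character to a length-`S` 0/1 indicator of compatible states, which
#' represents partial ambiguity (e.g. `R` = A or G) exactly. The engine
#' auto-upgrades a tip to partial mode when its sequence contains real
#' partial-ambiguity codes, so the compact fast path never loses
#' information.
#'
#' @param sequence a sequence string (or character vector of single
#'   characters).
#' @param mode `"compact"` or `"partial"`.
#' @param alphabet see [nucleotide_alphabet()].
#' @return compact: integer vector of 0-based codes; partial: an
#'   `S x n_sites` numeric 0/1 matrix.
#' @export
encode_tip <- function(sequence, mode = c("compact", "partial"),
                       alphabet = nucleotide_alphabet()) {
  mode <- match.arg(mode)
  ch <- if (length(sequence) == 1) strsplit(toupper(sequence), "")[[1]]
        else toupper(sequence)
  ch[ch == "U"] <- "T"
  S <- length(alphabet$states)
  legal <- names(alphabet$ambiguity)
  pos <- match(ch, legal)
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    pw_stop("illegal character '", ch[bad], "' at site ", bad)
  }
  if (mode == "compact") {
    # 0-based state index for unambiguous characters, sentinel S otherwise
    code <- vapply(alphabet$ambiguity, function(s)
      if (length(s) == 1L) s - 1L else S, integer(1))
    unname(code[pos])
  } else {
    M <- vapply(alphabet$ambiguity, function(s) {
      v <- numeric(S); v[s] <- 1; v
    }, numeric(S))
    unname(M[, pos, drop = FALSE])
  }
}

# TRUE when a sequence contains partial ambiguity (not representable by
# the compact "missing" sentinel).
needs_partials <- function(sequence, alphabet = nucleotide_alphabet()) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  ch[ch == "U"] <- "T"
  S <- length(alphabet$states)
  any(vapply(alphabet$ambiguity[ch], function(s) {
    length(s) > 1L && length(s) < S
  }, logical(1)))
}

#' Compress alignment columns into weighted unique site patterns
#'
#' Within each partition-defined subset, identical alignment columns are
#' collapsed to a single pattern whose weight counts the sites it
#' represents; patterns are ordered by first occurrence and subsets are
#' laid out contiguously in subset order. Likelihoods computed over
#' patterns weighted by their counts equal likelihoods over the original
#' sites, while the number of unique patterns is usually much smaller than
#' the alignment length.
#'
#' @param aln a `pw_alignment`.
#' @param subset_of_site optional integer vector assigning each site to a
#'   subset `1..K` (default: one subset).
#' @return an object of class `pw_patterns`: `patterns` (character matrix,
#'   taxa x patterns), `weights`, `subset_ranges` (K x 2 matrix of 1-based
#'   inclusive pattern ranges), `subset_of_site`, `pattern_of_site`,
#'   `taxon_names`, `alphabet`.
#' @export
compress_patterns <- function(aln, subset_of_site = NULL) {
  stopifnot(inherits(aln, "pw_alignment"))
  L <- aln$site_count
  if (is.null(subset_of_site)) subset_of_site <- rep(1L, L)
  if (length(subset_of_site) != L)
    pw_stop("subset_of_site must assign every site")
  K <- max(subset_of_site)
  if (!setequal(unique(subset_of_site), seq_len(K)))
    pw_stop("empty subset: subsets must be numbered 1..K with no gaps")
  mat <- do.call(rbind, strsplit(aln$sequences, ""))  # taxa x sites
  cols <- apply(mat, 2, paste, collapse = "")
  pat_list <- list(); w_list <- list()
  ranges <- matrix(0L, K, 2)
  pattern_of_site <- integer(L)
  offset <- 0L
  for (s in seq_len(K)) {
    idx <- which(subset_of_site == s)
    key <- cols[idx]
    uniq <- key[!duplicated(key)]
    m <- match(key, uniq)
    pat_list[[s]] <- mat[, idx[!duplicated(key)], drop = FALSE]
    w_list[[s]] <- tabulate(m, nbins = length(uniq))
    pattern_of_site[idx] <- offset + m
    ranges[s, ] <- c(offset + 1L, offset + length(uniq))
    offset <- offset + length(uniq)
  }
  structure(list(patterns = do.call(cbind, pat_list),
                 weights = unlist(w_list),
                 subset_ranges = ranges,
                 subset_of_site = subset_of_site,
                 pattern_of_site = pattern_of_site,
                 taxon_names = aln$taxon_names,
                 alphabet = aln$alphabet),
            class = "pw_patterns")
}

#' @export
print.pw_patterns <- function(x, ...) {
  cat(sprintf("<pw_patterns: %d taxa, %d patterns (%d sites), %d subset(s)>\n",
              nrow(x$patterns), ncol(x$patterns), sum(x$weights),
              nrow(x$subset_ranges)))
  invisible(x)
}

#' Read a partition config file
#'
#' Plain INI-style lines `name = ranges`, where ranges are comma-separated
#' 1-based inclusive site ranges, e.g. `gene1 = 1-450` or
#' `gene2 = 451-900, 1201-1300`. Lines starting with `#` and blank lines
#' are ignored. Every site must belong to exactly one subset.
#'
#' @param path config file.
#' @param site_count alignment length the partition must cover.
#' @return list with `names` (subset names) and `subset_of_site`
#'   (integer vector, 1-based subset index per site).
#' @export
read_partition_config <- function(path, site_count) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) pw_stop("no subsets defined in ", path)
  subset_of_site <- integer(site_count)
  nms <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) pw_stop("malformed partition line: ", ln)
    nms <- c(nms, trimws(parts[1]))
    k <- length(nms)
    for (rg in strsplit(trimws(parts[2]), ",")[[1]]) {
      ab <- as.integer(strsplit(trimws(rg), "-")[[1]])
      if (length(ab) == 1) ab <- c(ab, ab)
      if (anyNA(ab) || ab[1] < 1 || ab[2] > site_count || ab[1] > ab[2])
        pw_stop("bad site range '", rg, "' in subset ", nms[k])
      if (any(subset_of_site[ab[1]:ab[2]] != 0L))
        pw_stop("overlapping subsets at site ",
                which(subset_of_site[ab[1]:ab[2]] != 0L)[1] + ab[1] - 1L)
      subset_of_site[ab[1]:ab[2]] <- k
    }
  }
  if (any(subset_of_site == 0L))
    pw_stop("site ", which(subset_of_site == 0L)[1], " not covered by any subset")
  list(names = nms, subset_of_site = subset_of_site)
}
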