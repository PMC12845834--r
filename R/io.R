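# Readers/writers for the community structure formats. All on-disk formats
# are 1-based; internal coordinates are 0-based. Conversion happens here and
# nowhere else.

# Accept either a file path or in-memory text (single string with newlines,
# or a character vector of lines).
.as_lines <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    return(readLines(x, warn = FALSE))
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

#' Read RNA sequences from FASTA
#'
#' Parses standard (multi-record) FASTA via Biostrings, then validates each
#' record as an [rna_sequence()]: lowercase is uppercased, `T` becomes `U`,
#' and any character outside A, C, G, U, T, N is a parse error naming the
#' record and offset.
#'
#' @param x file path, or FASTA text (single string or character vector of
#'   lines).
#' @return list of `rna_sequence` objects.
#' @examples
#' parse_fasta(">s1\nGGGAAACCC")
#' @export
parse_fasta <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(trimws(lines[1L]), ">"))
    stop("malformed FASTA: first non-empty line is not a '>' header",
         call. = FALSE)
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  set <- Biostrings::readBStringSet(tmp)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (k in seq_along(set))
    out[[k]] <- rna_sequence(ids[k], as.character(set[[k]]))
  out
}

#' Write sequences to FASTA text
#' @param seqs a list of `rna_sequence` objects (or a single one).
#' @param path optional output file; when `NULL` the text is returned.
#' @return FASTA text (invisibly when written to `path`).
#' @export
write_fasta <- function(seqs, path = NULL) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  txt <- paste0(vapply(seqs, function(s)
    paste0(">", s$id, "\n", s$residues), character(1)), "\n",
    collapse = "")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

# ---- CT (6-column connectivity table) --------------------------------------

#' Parse a CT file
#'
#' Connectivity-table format: the first line carries the length (everything
#' after the first token is the title), followed by one row per residue with
#' at least 6 columns: index, base, previous, next, pairing partner (0 if
#' unpaired), index. Pairing must be reciprocal; self-pairing is an error.
#'
#' @param x file path or CT text.
#' @return `list(seq = rna_sequence, structure = secondary_structure)`.
#' @export
parse_ct <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CT input", call. = FALSE)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  L <- suppressWarnings(as.integer(hdr[1L]))
  if (is.na(L) || L < 1L)
    stop("CT header does not start with a positive length", call. = FALSE)
  id <- if (length(hdr) > 1L) paste(hdr[-1L], collapse = " ") else "ct"
  body <- lines[-1L]
  if (length(body) != L)
    stop("CT length mismatch: header says ", L, " residues, body has ",
         length(body), " rows", call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  ncol_ok <- vapply(fields, length, integer(1)) >= 6L
  if (!all(ncol_ok))
    stop("CT row ", which(!ncol_ok)[1L], " has fewer than 6 columns",
         call. = FALSE)
  bases <- vapply(fields, `[[`, character(1), 2L)
  partner <- vapply(fields, function(f) as.integer(f[[5L]]), integer(1))
  .pairs_from_partner(partner, L, "CT")
  seq <- rna_sequence(id, paste(bases, collapse = ""))
  list(seq = seq, structure = .pairs_from_partner(partner, L, "CT"))
}

# shared by CT and BPSEQ: 1-based partner column -> secondary_structure,
# with reciprocity and self-pairing checks
.pairs_from_partner <- function(partner, L, what) {
  if (any(is.na(partner)) || any(partner < 0L) || any(partner > L))
    stop(what, ": pairing column out of range", call. = FALSE)
  for (i in seq_len(L)) {
    j <- partner[i]
    if (j == 0L) next
    if (j == i) stop(what, ": row ", i, " pairs with itself", call. = FALSE)
    if (partner[j] != i)
      stop(what, ": non-reciprocal pairing, row ", i, " points to ", j,
           " but row ", j, " points to ", partner[j], call. = FALSE)
  }
  keep <- which(partner > 0L & seq_len(L) < partner)
  secondary_structure(L, cbind(keep - 1L, partner[keep] - 1L))
}

#' Write a CT file
#' @param seq an `rna_sequence`.
#' @param ss a `secondary_structure` with `ss$L == seq$L`.
#' @param path optional output file.
#' @return CT text (invisibly when written to `path`).
#' @export
write_ct <- function(seq, ss, path = NULL) {
  if (ss$L != seq$L) stop("sequence and structure lengths differ")
  partner <- .partner_vector(ss)
  idx <- seq_len(seq$L)
  bases <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  rows <- paste(idx, bases, idx - 1L, ifelse(idx == seq$L, 0L, idx + 1L),
                partner, idx)
  txt <- paste0(paste(c(paste(seq$L, seq$id), rows), collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

# 1-based partner vector (0 = unpaired) from a structure
.partner_vector <- function(ss) {
  partner <- integer(ss$L)
  if (nrow(ss$pairs)) {
    partner[ss$pairs[, 1L] + 1L] <- ss$pairs[, 2L] + 1L
    partner[ss$pairs[, 2L] + 1L] <- ss$pairs[, 1L] + 1L
  }
  partner
}

# ---- BPSEQ (3-column) ------------------------------------------------------

#' Parse a BPSEQ file
#'
#' Three whitespace-separated columns per residue: 1-based index, base,
#' 1-based pairing partner (0 if unpaired). Reciprocity is required and
#' self-pairing is an error.
#'
#' @param x file path or BPSEQ text.
#' @return `list(seq = rna_sequence, structure = secondary_structure)`.
#' @param id identifier for the returned sequence.
#' @export
parse_bpseq <- function(x, id = "bpseq") {
  lines <- .as_lines(x)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty BPSEQ input", call. = FALSE)
  fields <- strsplit(lines, "\\s+")
  ok <- vapply(fields, length, integer(1)) >= 3L
  if (!all(ok))
    stop("BPSEQ row ", which(!ok)[1L], " has fewer than 3 columns",
         call. = FALSE)
  idx <- vapply(fields, function(f) as.integer(f[[1L]]), integer(1))
  L <- length(lines)
  if (!identical(idx, seq_len(L)))
    stop("BPSEQ indices are not 1..L in order", call. = FALSE)
  bases <- vapply(fields, `[[`, character(1), 2L)
  partner <- vapply(fields, function(f) as.integer(f[[3L]]), integer(1))
  list(seq = rna_sequence(id, paste(bases, collapse = "")),
       structure = .pairs_from_partner(partner, L, "BPSEQ"))
}

#' Write a BPSEQ file
#' @inheritParams write_ct
#' @return BPSEQ text (invisibly when written to `path`).
#' @export
write_bpseq <- function(seq, ss, path = NULL) {
  if (ss$L != seq$L) stop("sequence and structure lengths differ")
  partner <- .partner_vector(ss)
  bases <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  txt <- paste0(paste(paste(seq_len(seq$L), bases, partner),
                      collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

# ---- dot-bracket with pseudoknot layers ------------------------------------

.db_open <- c("(", "[", "{", "<")
.db_close <- c(")", "]", "}", ">")

#' Parse a dot-bracket line
#'
#' Up to four bracket layers are supported: `()`, `[]`, `{}`, `<>`, matched
#' each with its own stack so crossing pairs (pseudoknots) across layers are
#' representable. Dots (and lowercase letters, for tolerance) are unpaired.
#'
#' @param line a single dot-bracket string.
#' @return a `secondary_structure`.
#' @examples
#' parse_dotbracket("(((...)))")$pairs
#' parse_dotbracket("([)]")$pairs # crossing pair, two layers
#' @export
parse_dotbracket <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  stacks <- rep(list(integer(0)), length(.db_open))
  pairs <- matrix(integer(0), ncol = 2L)
  for (pos in seq_len(L)) {
    ch <- chars[pos]
    layer <- match(ch, .db_open)
    if (!is.na(layer)) {
      stacks[[layer]] <- c(stacks[[layer]], pos)
      next
    }
    layer <- match(ch, .db_close)
    if (!is.na(layer)) {
      st <- stacks[[layer]]
      if (!length(st))
        stop("unbalanced '", ch, "' (layer ", layer, ") at position ", pos,
             call. = FALSE)
      pairs <- rbind(pairs, c(st[length(st)] - 1L, pos - 1L))
      stacks[[layer]] <- st[-length(st)]
      next
    }
    if (ch != "." && !grepl("^[a-zA-Z]$", ch))
      stop("illegal dot-bracket character '", ch, "' at position ", pos,
           call. = FALSE)
  }
  open_left <- vapply(stacks, length, integer(1))
  if (any(open_left > 0L)) {
    layer <- which(open_left > 0L)[1L]
    st <- stacks[[layer]]
    stop("unbalanced '", .db_open[layer], "' (layer ", layer,
         ") opened at position ", st[length(st)], call. = FALSE)
  }
  secondary_structure(L, pairs)
}

#' Write a structure as a dot-bracket line
#'
#' Layer assignment is canonicalised: pairs are processed in ascending
#' opening index and each is assigned to the lowest bracket layer in which
#' it does not cross a pair already assigned to that layer. Structures
#' needing more than four layers are rejected.
#'
#' @param ss a `secondary_structure`.
#' @return a dot-bracket string of length `ss$L`.
#' @export
write_dotbracket <- function(ss) {
  chars <- rep(".", ss$L)
  layers <- rep(list(matrix(numeric(0), ncol = 2L)), length(.db_open))
  p <- ss$pairs
  if (nrow(p)) p <- p[order(p[, 1L]), , drop = FALSE]
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1L]; j <- p[r, 2L]
    placed <- FALSE
    for (layer in seq_along(layers)) {
      q <- layers[[layer]]
      crosses <- nrow(q) && any((q[, 1L] < i & i < q[, 2L] & q[, 2L] < j) |
                                (i < q[, 1L] & q[, 1L] < j & j < q[, 2L]))
      if (!crosses) {
        layers[[layer]] <- rbind(q, c(i, j))
        chars[i + 1L] <- .db_open[layer]
        chars[j + 1L] <- .db_close[layer]
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("structure needs more than ", length(.db_open),
           " bracket layers; cannot be written as dot-bracket",
           call. = FALSE)
  }
  paste(chars, collapse = "")
}

# ---- dense score matrices ----------------------------------------------------

#' Read a dense L x L score matrix
#'
#' Whitespace/TAB-separated numeric matrix, one row per line; an optional
#' leading `# L=<int>` comment declares the dimension and is checked.
#'
#' @param x file path or matrix text.
#' @return numeric L x L matrix.
#' @export
read_score_matrix <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  L_declared <- NA_integer_
  if (length(lines) && startsWith(trimws(lines[1L]), "#")) {
    m <- regmatches(lines[1L], regexec("L\\s*=\\s*([0-9]+)", lines[1L]))[[1L]]
    if (length(m) == 2L) L_declared <- as.integer(m[2L])
    lines <- lines[-1L]
  }
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  n <- vapply(rows, length, integer(1))
  if (length(unique(n)) != 1L || length(rows) != n[1L])
    stop("score matrix is not square", call. = FALSE)
  M <- do.call(rbind, rows)
  if (!is.na(L_declared) && L_declared != nrow(M))
    stop("score matrix header declares L=", L_declared, " but body has ",
         nrow(M), " rows", call. = FALSE)
  if (any(!is.finite(M))) stop("score matrix has non-finite entries",
                               call. = FALSE)
  M
}

#' Write a dense score matrix with a `# L=` header
#' @param M numeric matrix.
#' @param path optional output file.
#' @return the text (invisibly when written to `path`).
#' @export
write_score_matrix <- function(M, path = NULL) {
  txt <- paste0("# L=", nrow(M), "\n",
                paste(apply(M, 1L, function(r)
                  paste(format(r, digits = 8, trim = TRUE),
                        collapse = "\t")), collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}
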