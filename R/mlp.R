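#' Default dialect for whitespace interaction-energy tables
#'
#' Column order, the label introducing the total (lattice) energy line, and
#' comment prefixes. The default mirrors PixelC-style .MLP content: centroid
#' distance followed by Coulombic, polarization, dispersion, repulsion and
#' total energies, with optional trailing symmetry-operation text.
#'
#' @param columns column names, in file order.
#' @param total_key label of the lattice-energy line (case-insensitive).
#' @param comment lines starting with any of these prefixes are skipped.
#' @export
mlp_dialect <- function(columns = c("distance", "coulomb", "polarization",
                                    "dispersion", "repulsion", "total"),
                        total_key = "toto",
                        comment = c("#", "!")) {
  list(columns = columns, total_key = total_key, comment = comment)
}

.ascii_minus <- function(x) gsub("−", "-", x)

#' Parse a PixelC-style whitespace energy table
#'
#' Rows are whitespace-delimited with at least `length(dialect$columns)`
#' numeric fields; anything after the numeric fields is kept as symmetry
#' text. The lattice energy is taken from the line whose first token matches
#' the dialect's `total_key`. Malformed rows are kept out of the result and
#' reported with their line numbers. Rows whose components fail to add up to
#' the total within `closure_tol` draw a warning.
#'
#' @param text table text (string, lines, or file path).
#' @param dialect a [mlp_dialect()].
#' @param closure_tol component-closure tolerance in kJ/mol.
#' @return list with `rows` (data.frame of the dialect's columns plus
#'   `symop_text` and `line`), `toto` (lattice energy, NA if absent) and
#'   `problems` (character).
#' @export
parse_energy_table <- function(text, dialect = mlp_dialect(), closure_tol = 0.15) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  lines <- .ascii_minus(lines)
  ncol_ <- length(dialect$columns)
  rows <- list()
  problems <- character(0)
  toto <- NA_real_
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw)) next
    if (any(startsWith(raw, dialect$comment))) next
    toks <- strsplit(raw, "[ \t]+")[[1]]
    if (tolower(toks[1]) == tolower(dialect$total_key)) {
      num <- suppressWarnings(as.numeric(toks[-1]))
      num <- num[!is.na(num)]
      if (length(num) >= 1) toto <- num[1]
      else problems <- c(problems, sprintf("line %d: total-energy line has no number", ln))
      next
    }
    vals <- suppressWarnings(as.numeric(toks))
    lead <- which(is.na(vals))
    n_numeric <- if (length(lead) == 0) length(vals) else lead[1] - 1L
    if (n_numeric == 0) next  # header / prose line
    if (n_numeric < ncol_) {
      problems <- c(problems, sprintf(
        "line %d: expected %d numeric fields, found %d", ln, ncol_, n_numeric))
      next
    }
    row <- as.list(vals[seq_len(ncol_)])
    names(row) <- dialect$columns
    row$symop_text <- if (length(toks) > ncol_)
      paste(toks[(ncol_ + 1):length(toks)], collapse = " ") else ""
    row$line <- ln
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no numeric rows found in energy table")
  rows <- do.call(rbind, rows)
  if (all(c("coulomb", "polarization", "dispersion", "repulsion", "total")
          %in% names(rows))) {
    dev <- abs(rows$total - (rows$coulomb + rows$polarization +
                             rows$dispersion + rows$repulsion))
    if (any(dev > closure_tol)) {
      warning(sprintf("%d row(s) violate component closure by up to %.2f kJ/mol",
                      sum(dev > closure_tol), max(dev)))
    }
  }
  if (is.na(toto)) {
    warning("no '", dialect$total_key, "' total-energy line found")
  }
  list(rows = rows, toto = toto, problems = problems)
}

#' Annotate an energy table with ORTEP codes via centroid matching
#'
#' Greedily matches each table row to the pair with the nearest centroid
#' distance (within `tolerance`), filling `code`, `standard_symop` and
#' `match_error`, and copies the row energies onto the matched pairs for
#' downstream use (half-sum verification, lattice-energy estimates).
#'
#' @param parsed output of [parse_energy_table()].
#' @param pairs a `pair_table` computed from the same structure, ideally
#'   grouped with [pair_multiplicities()].
#' @param tolerance maximum centroid-distance discrepancy in Angstrom.
#' @return an `annotated_table`: list with `rows` (sorted by distance, with
#'   annotation columns), `toto`, and `pairs` (with `total` energies filled
#'   on matched rows).
#' @export
annotate_table <- function(parsed, pairs, tolerance = 0.01) {
  rows <- parsed$rows
  rows$code <- NA_character_
  rows$standard_symop <- NA_character_
  rows$match_error <- NA_real_
  rows$pair_row <- NA_integer_
  structure_ <- attr(pairs, "structure")
  if (nrow(rows) > 0 && nrow(pairs) > 0) {
    cand <- expand.grid(r = seq_len(nrow(rows)), p = seq_len(nrow(pairs)))
    cand$err <- abs(rows$distance[cand$r] - pairs$distance[cand$p])
    cand <- cand[cand$err <= tolerance, , drop = FALSE]
    cand <- cand[order(cand$err), , drop = FALSE]
    used_r <- rep(FALSE, nrow(rows)); used_p <- rep(FALSE, nrow(pairs))
    for (i in seq_len(nrow(cand))) {
      r <- cand$r[i]; p <- cand$p[i]
      if (used_r[r] || used_p[p]) next
      rows$code[r] <- pairs$code[p]
      rows$match_error[r] <- cand$err[i]
      rows$pair_row[r] <- p
      if (!is.na(pairs$code[p])) {
        rows$standard_symop[r] <- ortep_to_standard(
          list(t = c(pairs$tx[p], pairs$ty[p], pairs$tz[p]), op_index = pairs$op[p]),
          structure_)
      }
      used_r[r] <- TRUE; used_p[p] <- TRUE
    }
  }
  if (any(is.na(rows$pair_row))) {
    warning(sprintf(paste0("%d table row(s) have no pair within %.3g Angstrom; ",
                           "the default 20 Angstrom limit on the centroid scan ",
                           "should be increased"),
                    sum(is.na(rows$pair_row)), tolerance))
  }
  for (col in c("coulomb", "polarization", "dispersion", "repulsion", "total")) {
    if (!is.null(rows[[col]])) {
      if (is.null(pairs[[col]])) pairs[[col]] <- NA_real_
      ok <- !is.na(rows$pair_row)
      pairs[[col]][rows$pair_row[ok]] <- rows[[col]][ok]
    }
  }
  rows <- rows[order(rows$distance), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(rows = rows, toto = parsed$toto, pairs = pairs),
            class = "annotated_table")
}

#' Verify the lattice-energy half-sum against 'toto'
#'
#' Recomputes half the multiplicity-weighted sum of row total energies (per
#' reference residue) and reports the difference from the table's stated
#' total. When several table rows are matched into the same symmetry orbit,
#' the orbit's multiplicity is shared between them, so tables listing either
#' one row per orbit or one row per neighbor image both verify.
#'
#' @param annotated an `annotated_table` from [annotate_table()].
#' @return list with `recomputed`, `toto`, `difference` (recomputed - toto)
#'   and `n_unmatched` rows excluded for lack of a pair match.
#' @export
verify_toto <- function(annotated) {
  rows <- annotated$rows
  pairs <- annotated$pairs
  matched <- !is.na(rows$pair_row)
  w <- rep(1, nrow(rows))
  if (!is.null(pairs$group)) {
    grp <- pairs$group[rows$pair_row[matched]]
    mult <- pairs$multiplicity[rows$pair_row[matched]]
    per_grp <- table(grp)
    w[matched] <- mult / as.numeric(per_grp[as.character(grp)])
  }
  nres <- if (nrow(pairs) > 0) length(unique(pairs$ref)) else 1L
  recomputed <- 0.5 * sum(w[matched] * rows$total[matched]) / nres
  list(recomputed = recomputed, toto = annotated$toto,
       difference = recomputed - annotated$toto,
       n_unmatched = sum(!matched))
}

#' Write an annotated interaction table as spreadsheet-compatible CSV
#'
#' @param annotated an `annotated_table` (or the list from
#'   [parse_energy_table()]).
#' @param path file path, or `NULL` to return the text.
#' @return the CSV text.
#' @export
write_interaction_csv <- function(annotated, path = NULL) {
  rows <- annotated$rows
  fmt_num <- function(x, digits) ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
  out <- data.frame(
    distance = fmt_num(rows$distance, 3),
    coulomb = fmt_num(rows$coulomb, 2),
    polarization = fmt_num(rows$polarization, 2),
    dispersion = fmt_num(rows$dispersion, 2),
    repulsion = fmt_num(rows$repulsion, 2),
    total = fmt_num(rows$total, 2),
    code = if (is.null(rows$code)) "" else ifelse(is.na(rows$code), "", rows$code),
    standard_symop = if (is.null(rows$standard_symop)) "" else
      ifelse(is.na(rows$standard_symop), "", paste0("\"", rows$standard_symop, "\"")),
    match_error = if (is.null(rows$match_error)) "" else fmt_num(rows$match_error, 4),
    stringsAsFactors = FALSE)
  txt <- paste0(paste(colnames(out), collapse = ","), "\n")
  if (nrow(out) > 0) {
    txt <- paste0(txt, paste(apply(out, 1, paste, collapse = ","), collapse = "\n"), "\n")
  }
  if (!is.na(annotated$toto)) {
    txt <- paste0(txt, sprintf("toto,%.2f\n", annotated$toto))
  }
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

#' Read back a CSV written by [write_interaction_csv()]
#'
#' @param text CSV text or file path.
#' @return list with `rows` (data.frame) and `toto`.
#' @export
read_interaction_csv <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  toto <- NA_real_
  toto_line <- grepl("^toto,", lines)
  if (any(toto_line)) {
    toto <- as.numeric(sub("^toto,", "", lines[toto_line][1]))
    lines <- lines[!toto_line]
  }
  rows <- utils::read.csv(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = c(code = "character"))
  list(rows = rows, toto = toto)
}
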