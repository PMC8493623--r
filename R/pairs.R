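#' Encode an ORTEP-type symmetry code
#'
#' The code is three digits giving the unit-cell translations along x, y and z
#' plus 5, followed by the two-digit symmetry-operation number: `55501` is the
#' identity operation with no translation.
#'
#' @param t integer 3-vector of cell translations, each in `[-4, 4]`.
#' @param op_index 1-based operation number, 1..99.
#' @return a 5-character code string.
#' @examples
#' encode_ortep(c(0, 0, 0), 1)  # "55501"
#' @export
encode_ortep <- function(t, op_index) {
  t <- as.integer(round(t))
  op_index <- as.integer(op_index)
  if (length(t) != 3 || any(abs(t) > 4)) {
    stop("ORTEP translations must be integer 3-vector in [-4, 4], got ",
         paste(t, collapse = ","))
  }
  if (op_index < 1 || op_index > 99) {
    stop("ORTEP operation number must be in 1..99, got ", op_index)
  }
  paste0(paste0(t + 5L, collapse = ""), sprintf("%02d", op_index))
}

#' @rdname encode_ortep
#' @param code a code string of 5 or more digits.
#' @return for `decode_ortep`, a list with `t` (integer 3-vector) and
#'   `op_index`.
#' @export
decode_ortep <- function(code) {
  code <- as.character(code)
  if (!grepl("^[0-9]{5,}$", code)) {
    stop("ORTEP code must be 5+ digits, got ", dQuote(code))
  }
  digs <- as.integer(strsplit(code, "")[[1]])
  t <- digs[1:3] - 5L
  op_index <- as.integer(substr(code, 4, nchar(code)))
  if (op_index < 1) stop("ORTEP operation number must be >= 1 in ", dQuote(code))
  list(t = t, op_index = op_index)
}

#' Translate an ORTEP code to a standard xyz symmetry string
#'
#' Note the operation numbering is the order of operations in this package's
#' parsed structure (CIF file order), which may not match numbering used by
#' other programs.
#'
#' @param code an ORTEP code string (or list from [decode_ortep()]).
#' @param structure a `crystal_structure`.
#' @return an xyz string such as `"1-x, 1-y, 2-z"`.
#' @export
ortep_to_standard <- function(code, structure) {
  dec <- if (is.character(code)) decode_ortep(code) else code
  if (dec$op_index > length(structure$operations)) {
    stop(sprintf(paste0("operation number %d not present in structure (%d operations); ",
                        "note: ORTEP operation numbers may not match those in the CIF"),
                 dec$op_index, length(structure$operations)))
  }
  format_symop_xyz(structure$operations[[dec$op_index]], dec$t)
}

.interplanar_spacings <- function(cell) {
  mi <- solve(cell_matrix(cell))
  # distance between lattice planes of constant fractional coordinate i
  1 / sqrt(rowSums(mi^2))
}

#' Enumerate symmetry-related molecular pairs within a centroid cutoff
#'
#' For every reference molecule, every symmetry image (operation + integer
#' cell translation) of every molecule whose mass-weighted centroid lies
#' within `cutoff` Angstrom of the reference centroid is listed once, tagged
#' with its ORTEP code. The self image is excluded. Translation search bounds
#' are derived from the interplanar spacings, which provably covers all
#' images within the cutoff for arbitrarily skewed cells.
#'
#' @param structure a `crystal_structure`.
#' @param molecules list of completed [molecule()]s (see
#'   [complete_molecules()]).
#' @param cutoff centroid-distance limit in Angstrom (default 20).
#' @return a `pair_table`: data.frame with columns `ref`, `neighbor`, `op`,
#'   `tx`, `ty`, `tz`, `code`, `distance`, `multiplicity`, `match_error`,
#'   sorted by ascending distance; attributes `cutoff` and `structure`.
#' @export
enumerate_pairs <- function(structure, molecules, cutoff = 20) {
  stopifnot(cutoff > 0)
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  cell <- structure$cell
  g <- metric_tensor(cell)
  cf <- t(vapply(molecules, function(m)
    cart_to_frac(cell, mass_weighted_centroid(m)), numeric(3)))
  spac <- .interplanar_spacings(cell)
  bound <- ceiling(cutoff / spac) + 1

  rows <- list()
  nres <- length(molecules)
  for (r in seq_len(nres)) {
    for (k in seq_along(structure$operations)) {
      op <- structure$operations[[k]]
      for (s in seq_len(nres)) {
        base <- apply_symop(op, cf[s, ])
        rng <- lapply(1:3, function(i) {
          ctr <- cf[r, i] - base[i]
          seq(floor(ctr - bound[i]), ceiling(ctr + bound[i]))
        })
        grid <- as.matrix(expand.grid(tx = rng[[1]], ty = rng[[2]], tz = rng[[3]]))
        dp <- sweep(grid, 2, cf[r, ] - base, "-")  # image - ref in fractional
        d2 <- rowSums((dp %*% g) * dp)
        keep <- which(d2 <= cutoff^2 + 1e-9 & d2 > 1e-12)
        if (length(keep) > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            ref = r, neighbor = s, op = k,
            tx = as.integer(grid[keep, 1]), ty = as.integer(grid[keep, 2]),
            tz = as.integer(grid[keep, 3]),
            distance = sqrt(d2[keep]), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    warning("no pairs found within cutoff ", cutoff, " Angstrom")
    tab <- data.frame(ref = integer(0), neighbor = integer(0), op = integer(0),
                      tx = integer(0), ty = integer(0), tz = integer(0),
                      code = character(0), distance = numeric(0),
                      multiplicity = integer(0), match_error = numeric(0))
  } else {
    tab <- do.call(rbind, rows)
    tab$code <- vapply(seq_len(nrow(tab)), function(i) {
      if (all(abs(c(tab$tx[i], tab$ty[i], tab$tz[i])) <= 4) && tab$op[i] <= 99) {
        encode_ortep(c(tab$tx[i], tab$ty[i], tab$tz[i]), tab$op[i])
      } else NA_character_
    }, "")
    tab$multiplicity <- NA_integer_
    tab$match_error <- NA_real_
    tab <- tab[order(tab$distance, tab$ref, tab$neighbor, tab$op, tab$tx, tab$ty, tab$tz), ]
    rownames(tab) <- NULL
  }
  attr(tab, "cutoff") <- cutoff
  attr(tab, "structure") <- structure
  class(tab) <- c("pair_table", "data.frame")
  tab
}

#' @export
print.pair_table <- function(x, n = 10, ...) {
  cat(sprintf("<pair_table> %d pairs within %.1f Angstrom\n",
              nrow(x), attr(x, "cutoff")))
  print.data.frame(utils::head(x, n), digits = 5)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Invert a pair's symmetry relationship
#'
#' If molecule B is A's neighbor under (operation k, shift n), A is B's
#' neighbor under the inverse transformation; this returns its (operation
#' index, integer shift) in terms of the structure's own operator list.
#'
#' @param structure a `crystal_structure`.
#' @param op_index operation number of the forward relationship.
#' @param t integer cell translation of the forward relationship.
#' @return list with `op_index` and `t` of the inverse.
#' @export
invert_pair_code <- function(structure, op_index, t) {
  op <- structure$operations[[op_index]]
  rinv <- solve(op$rotation)
  tinv <- -as.numeric(rinv %*% (op$translation + t))
  for (cand in structure$operations) {
    if (all(abs(cand$rotation - rinv) < 1e-8)) {
      m <- tinv - cand$translation
      if (all(abs(m - round(m)) < 1e-8)) {
        return(list(op_index = cand$index, t = as.integer(round(m))))
      }
    }
  }
  stop("inverse operation not found in structure's operator list")
}

#' Match a pair table against external centroid distances
#'
#' Greedy nearest-distance matching; each matched row receives
#' `match_error = |d_table - d_external|`. External distances with no table
#' row within `tolerance` trigger a warning suggesting the centroid-scan
#' cutoff be increased.
#'
#' @param table a `pair_table`.
#' @param external_distances numeric vector of centroid distances (Angstrom).
#' @param tolerance maximum distance discrepancy counted as a match.
#' @return the table with `match_error` filled for matched rows.
#' @export
match_centroids <- function(table, external_distances, tolerance = 0.01) {
  ext <- sort(external_distances)
  used_row <- rep(FALSE, nrow(table))
  used_ext <- rep(FALSE, length(ext))
  if (nrow(table) > 0 && length(ext) > 0) {
    cand <- expand.grid(row = seq_len(nrow(table)), e = seq_along(ext))
    cand$err <- abs(table$distance[cand$row] - ext[cand$e])
    cand <- cand[cand$err <= tolerance, , drop = FALSE]
    cand <- cand[order(cand$err), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      r <- cand$row[i]; e <- cand$e[i]
      if (!used_row[r] && !used_ext[e]) {
        table$match_error[r] <- cand$err[i]
        used_row[r] <- TRUE
        used_ext[e] <- TRUE
      }
    }
  }
  if (any(!used_ext)) {
    warning(sprintf(paste0("%d external centroid distance(s) unmatched (e.g. %.3f Angstrom); ",
                           "the default 20 Angstrom limit on the centroid scan should be increased"),
                    sum(!used_ext), ext[!used_ext][1]))
  }
  table
}

#' Group symmetry-equivalent pairs and fill multiplicities
#'
#' Rows with the same unordered residue pair and centroid distance (within
#' 1e-4 Angstrom) are treated as one orbit of symmetry-equivalent neighbor
#' images (forward and inverse codes are each other's inverses within such a
#' group). `multiplicity` is the group size; `group` numbers the orbits and
#' `representative` marks the first row of each.
#'
#' @param table a `pair_table`.
#' @return the table with `multiplicity`, `group` and `representative` filled.
#' @export
pair_multiplicities <- function(table) {
  if (nrow(table) == 0) return(table)
  key <- paste(pmin(table$ref, table$neighbor), pmax(table$ref, table$neighbor),
               sprintf("%.4f", table$distance))
  groups <- match(key, unique(key))
  table$group <- groups
  table$multiplicity <- as.integer(ave(groups, groups, FUN = length))
  table$representative <- !duplicated(groups)
  table
}

#' Write a pair table as spreadsheet-compatible CSV
#'
#' @param table a `pair_table`, ideally after [pair_multiplicities()].
#' @param path file to write, or `NULL` to return the text.
#' @return the CSV text, invisibly when written to a file.
#' @export
write_pairs_csv <- function(table, path = NULL) {
  structure <- attr(table, "structure")
  std <- vapply(seq_len(nrow(table)), function(i) {
    if (is.na(table$code[i])) return("")
    ortep_to_standard(list(t = c(table$tx[i], table$ty[i], table$tz[i]),
                           op_index = table$op[i]), structure)
  }, "")
  out <- data.frame(
    ref = table$ref, neighbor = table$neighbor,
    code = ifelse(is.na(table$code), "", table$code),
    standard_symop = ifelse(nzchar(std), paste0("\"", std, "\""), ""),
    distance_A = sprintf("%.3f", table$distance),
    multiplicity = if (all(is.na(table$multiplicity))) "" else table$multiplicity,
    stringsAsFactors = FALSE
  )
  txt <- paste0(paste(colnames(out), collapse = ","), "\n",
                paste(apply(out, 1, paste, collapse = ","), collapse = "\n"),
                if (nrow(out) > 0) "\n" else "")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}
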