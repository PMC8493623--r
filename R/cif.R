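#' Unit cell constructor
#'
#' @param a,b,c cell edge lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return an object of class `unit_cell`.
#' @examples
#' unit_cell(10, 20, 30)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) stop("cell parameters must be finite numbers")
  if (any(p[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(p[4:6] <= 0) || any(p[4:6] >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  cell <- structure(as.list(p), class = "unit_cell")
  if (cell_volume(cell) <= 0 || !is.finite(cell_volume(cell))) {
    stop("degenerate cell: metric tensor is not positive definite")
  }
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Orthogonalization matrix of a unit cell
#'
#' Returns the 3x3 matrix M with cartesian = M %*% fractional, using the
#' standard crystallographic frame: a along x, b in the xy-plane.
#'
#' @param cell a [unit_cell()].
#' @return 3x3 numeric matrix (Angstrom).
#' @export
cell_matrix <- function(cell) {
  deg <- pi / 180
  ca <- cos(cell$alpha * deg); cb <- cos(cell$beta * deg)
  cg <- cos(cell$gamma * deg); sg <- sin(cell$gamma * deg)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("degenerate cell: angles incompatible")
  v <- sqrt(v2)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' @rdname cell_matrix
#' @export
cell_volume <- function(cell) {
  deg <- pi / 180
  ca <- cos(cell$alpha * deg); cb <- cos(cell$beta * deg); cg <- cos(cell$gamma * deg)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) return(NaN)
  cell$a * cell$b * cell$c * sqrt(v2)
}

#' Metric tensor G such that d^2 = t(dp) %*% G %*% dp for fractional dp
#' @rdname cell_matrix
#' @export
metric_tensor <- function(cell) {
  m <- cell_matrix(cell)
  crossprod(m)
}

#' Convert fractional to Cartesian coordinates (and back)
#'
#' `p` may be a length-3 vector or an n x 3 matrix (one point per row).
#'
#' @param cell a [unit_cell()].
#' @param p fractional (or Cartesian, for the inverse) coordinates.
#' @return coordinates in the same shape as `p`.
#' @export
frac_to_cart <- function(cell, p) {
  m <- cell_matrix(cell)
  if (is.matrix(p)) t(m %*% t(p)) else as.numeric(m %*% p)
}

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(cell, p) {
  mi <- solve(cell_matrix(cell))
  if (is.matrix(p)) t(mi %*% t(p)) else as.numeric(mi %*% p)
}

# ---------------------------------------------------------------------------
# Symmetry operations
# ---------------------------------------------------------------------------

.snap_rational <- function(x, denom = 24L, tol = 1e-6) {
  r <- round(x * denom) / denom
  ifelse(abs(r - x) < tol, r, x)
}

#' Construct a symmetry operation
#'
#' The translation is stored reduced to `[0, 1)`; the integer part that was
#' stripped off is kept in `shift` so that strings such as `"2-z"` round-trip
#' through [format_symop_xyz()].
#'
#' @param rotation 3x3 matrix, determinant +-1.
#' @param translation fractional translation 3-vector (raw, any value).
#' @param index 1-based operation number.
#' @return an object of class `symop`.
#' @export
symop <- function(rotation, translation = c(0, 0, 0), index = 1L) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  d <- det(rotation)
  if (abs(abs(d) - 1) > 1e-8) stop("symmetry operation rotation must have determinant +-1")
  translation <- .snap_rational(as.numeric(translation))
  reduced <- translation %% 1
  shift <- as.integer(round(translation - reduced))
  structure(list(rotation = rotation, translation = reduced,
                 shift = shift, index = as.integer(index)),
            class = "symop")
}

#' @export
print.symop <- function(x, ...) {
  cat(sprintf("<symop %d> %s\n", x$index, format_symop_xyz(x)))
  invisible(x)
}

#' Parse an xyz-style symmetry operation string
#'
#' Accepts strings such as `"x, y, z"`, `"1/2+x, 1/2-y, z"` or
#' `"1-x, 1-y, 2-z"`. The integer part of the raw translation is preserved in
#' the `shift` field so the original string is recoverable.
#'
#' @param s one xyz triplet string.
#' @param index operation number to record.
#' @return a [symop()].
#' @export
parse_symop_xyz <- function(s, index = 1L) {
  if (!is.character(s) || length(s) != 1L) stop("expected a single string")
  if (grepl("[^xyzXYZ0-9+*/., \t-]", s)) {
    bad <- regmatches(s, regexpr("[^xyzXYZ0-9+*/., \t-]", s))
    stop(sprintf("cannot parse symmetry string %s: illegal character '%s' at position %d",
                 dQuote(s), bad, regexpr("[^xyzXYZ0-9+*/., \t-]", s)))
  }
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop(sprintf("cannot parse symmetry string %s: expected 3 comma-separated components, got %d",
                 dQuote(s), length(parts)))
  }
  rot <- matrix(0, 3, 3)
  tra <- numeric(3)
  env0 <- list(x = 0, y = 0, z = 0)
  for (i in 1:3) {
    expr <- tryCatch(parse(text = tolower(parts[i]))[[1]],
                     error = function(e) stop(sprintf(
                       "cannot parse symmetry string %s: component %d (%s) is malformed",
                       dQuote(s), i, dQuote(trimws(parts[i]))), call. = FALSE))
    f <- function(vals) eval(expr, vals)
    t0 <- f(env0)
    tra[i] <- t0
    rot[i, 1] <- f(list(x = 1, y = 0, z = 0)) - t0
    rot[i, 2] <- f(list(x = 0, y = 1, z = 0)) - t0
    rot[i, 3] <- f(list(x = 0, y = 0, z = 1)) - t0
  }
  rot[] <- .snap_rational(rot)
  symop(rot, tra, index)
}

.format_frac <- function(x) {
  # format a rational constant: integers plainly, else n/d with small d
  if (abs(x - round(x)) < 1e-9) return(sprintf("%d", as.integer(round(x))))
  for (d in c(2L, 3L, 4L, 6L, 8L, 12L, 24L)) {
    n <- x * d
    if (abs(n - round(n)) < 1e-9) return(sprintf("%d/%d", as.integer(round(n)), d))
  }
  format(x)
}

#' Format a symmetry operation as an xyz string
#'
#' The operation's own reduced translation and preserved integer shift are
#' combined with `extra_translation` (ORTEP-style whole unit-cell shifts).
#'
#' @param op a [symop()].
#' @param extra_translation integer 3-vector of additional cell translations.
#' @return a string like `"1-x, 1-y, 2-z"`.
#' @export
format_symop_xyz <- function(op, extra_translation = c(0L, 0L, 0L)) {
  vars <- c("x", "y", "z")
  out <- character(3)
  for (i in 1:3) {
    const <- op$translation[i] + op$shift[i] + extra_translation[i]
    terms <- ""
    for (j in 1:3) {
      cf <- op$rotation[i, j]
      if (abs(cf) < 1e-9) next
      if (abs(abs(cf) - 1) > 1e-9) {
        stop("cannot format non-unit rotation coefficient ", cf)
      }
      sign_str <- if (cf > 0) "+" else "-"
      terms <- paste0(terms, sign_str, vars[j])
    }
    if (abs(const) > 1e-9) {
      out[i] <- paste0(.format_frac(const), terms)
    } else {
      out[i] <- sub("^\\+", "", terms)
    }
    if (out[i] == "") out[i] <- "0"
  }
  paste(out, collapse = ", ")
}

#' Apply a symmetry operation to fractional coordinates
#'
#' @param op a [symop()].
#' @param p fractional 3-vector or n x 3 matrix.
#' @param shift additional integer cell translation.
#' @return transformed fractional coordinates, same shape as `p`.
#' @export
apply_symop <- function(op, p, shift = c(0, 0, 0)) {
  t_all <- op$translation + shift
  if (is.matrix(p)) {
    sweep(t(op$rotation %*% t(p)), 2, t_all, "+")
  } else {
    as.numeric(op$rotation %*% p) + t_all
  }
}

#' Compose two symmetry operations (g1 after g2)
#' @keywords internal
compose_symops <- function(g1, g2) {
  rot <- g1$rotation %*% g2$rotation
  tra <- as.numeric(g1$rotation %*% (g2$translation + g2$shift)) +
    g1$translation + g1$shift
  symop(rot, tra, 0L)
}

symop_is_identity <- function(op, mod_lattice = FALSE) {
  rot_ok <- all(abs(op$rotation - diag(3)) < 1e-8)
  t_all <- op$translation + if (mod_lattice) 0 else op$shift
  t_ok <- if (mod_lattice) all(abs(op$translation) < 1e-8) else all(abs(t_all) < 1e-8)
  rot_ok && t_ok
}

# ---------------------------------------------------------------------------
# CIF parsing
# ---------------------------------------------------------------------------

# built-in operator lists for a few space groups recognized by name, used
# when a CIF carries a name but no symmetry loop
.known_spacegroups <- list(
  "P 1"      = c("x, y, z"),
  "P -1"     = c("x, y, z", "-x, -y, -z"),
  "P 21"     = c("x, y, z", "-x, 1/2+y, -z"),
  "P 21/c"   = c("x, y, z", "-x, 1/2+y, 1/2-z", "-x, -y, -z", "x, 1/2-y, 1/2+z"),
  "P 21/n"   = c("x, y, z", "1/2-x, 1/2+y, 1/2-z", "-x, -y, -z", "1/2+x, 1/2-y, 1/2+z")
)

.sg_key <- function(name) toupper(gsub("[ _]", "", name))

.cif_tokenize_line <- function(line) {
  line <- sub("#.*$", "", line)
  tokens <- character(0)
  rest <- trimws(line)
  while (nzchar(rest)) {
    if (substr(rest, 1, 1) %in% c("'", '"')) {
      q <- substr(rest, 1, 1)
      end <- regexpr(paste0(q, "(\\s|$)"), substr(rest, 2, nchar(rest)))
      if (end < 0) { tokens <- c(tokens, substr(rest, 2, nchar(rest))); rest <- "" }
      else {
        tokens <- c(tokens, substr(rest, 2, end))
        rest <- trimws(substr(rest, end + 2, nchar(rest)))
      }
    } else {
      sp <- regexpr("\\s", rest)
      if (sp < 0) { tokens <- c(tokens, rest); rest <- "" }
      else {
        tokens <- c(tokens, substr(rest, 1, sp - 1))
        rest <- trimws(substr(rest, sp + 1, nchar(rest)))
      }
    }
  }
  tokens
}

# low-level CIF 1.1 reader: returns list(items = named list, loops = list of
# data.frames with tag-named columns)
.cif_scan <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  items <- list()
  loops <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#") || startsWith(tolower(line), "data_")) {
      i <- i + 1L; next
    }
    if (tolower(line) == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, tolower(trimws(lines[i])))
        i <- i + 1L
      }
      values <- character(0)
      while (i <= n) {
        l2 <- trimws(lines[i])
        if (!nzchar(l2) || startsWith(l2, "#")) { i <- i + 1L; next }
        if (grepl("^(_|loop_|data_)", tolower(l2))) break
        values <- c(values, .cif_tokenize_line(lines[i]))
        i <- i + 1L
      }
      if (length(tags) > 0 && length(values) %% length(tags) == 0 && length(values) > 0) {
        m <- matrix(values, ncol = length(tags), byrow = TRUE)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- tags
        loops[[length(loops) + 1L]] <- df
      } else if (length(tags) > 0) {
        stop(sprintf("CIF loop with tags [%s]: %d values do not fill rows of %d",
                     paste(tags, collapse = ", "), length(values), length(tags)))
      }
      next
    }
    if (startsWith(line, "_")) {
      toks <- .cif_tokenize_line(line)
      tag <- tolower(toks[1])
      if (length(toks) >= 2) {
        items[[tag]] <- paste(toks[-1], collapse = " ")
      } else if (i + 1L <= n && startsWith(trimws(lines[i + 1L]), ";")) {
        # multi-line text field: skip to closing semicolon
        j <- i + 2L
        val <- character(0)
        while (j <= n && !startsWith(trimws(lines[j]), ";")) {
          val <- c(val, lines[j]); j <- j + 1L
        }
        items[[tag]] <- paste(val, collapse = "\n")
        i <- j
      } else if (i + 1L <= n) {
        items[[tag]] <- trimws(lines[i + 1L])
        i <- i + 1L
      }
    }
    i <- i + 1L
  }
  list(items = items, loops = loops)
}

.cif_number <- function(x) {
  # strip standard-uncertainty parentheses: "1.234(5)" -> 1.234
  suppressWarnings(as.numeric(sub("\\(.*\\)", "", x)))
}

.find_loop <- function(loops, tag_options) {
  for (lp in loops) {
    if (any(tag_options %in% names(lp))) return(lp)
  }
  NULL
}

#' Parse a CIF document into a crystal structure
#'
#' Understands the CSD dialect and common SHELXL tag spellings: both
#' `_symmetry_equiv_pos_as_xyz` and `_space_group_symop_operation_xyz`
#' symmetry loops, and both `_symmetry_space_group_name_H-M` and
#' `_space_group_name_H-M_alt`. If no symmetry loop is present but the
#' space-group name is one of a few recognized groups, the operator list is
#' generated from the name.
#'
#' @param text a CIF document, as a single string or character vector of lines.
#' @return an object of class `crystal_structure` with fields `cell`,
#'   `operations`, `sites`, `space_group_name`, `z_prime_hint`.
#' @export
parse_cif <- function(text) {
  scan <- .cif_scan(text)
  items <- scan$items

  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c")
  if (!all(need %in% names(items))) {
    stop("CIF parse error: missing cell parameters (",
         paste(setdiff(need, names(items)), collapse = ", "), ")")
  }
  cell <- unit_cell(
    .cif_number(items[["_cell_length_a"]]),
    .cif_number(items[["_cell_length_b"]]),
    .cif_number(items[["_cell_length_c"]]),
    if (!is.null(items[["_cell_angle_alpha"]])) .cif_number(items[["_cell_angle_alpha"]]) else 90,
    if (!is.null(items[["_cell_angle_beta"]]))  .cif_number(items[["_cell_angle_beta"]])  else 90,
    if (!is.null(items[["_cell_angle_gamma"]])) .cif_number(items[["_cell_angle_gamma"]]) else 90
  )

  sg_name <- items[["_symmetry_space_group_name_h-m"]]
  if (is.null(sg_name)) sg_name <- items[["_space_group_name_h-m_alt"]]
  if (is.null(sg_name)) sg_name <- ""

  xyz_tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  symloop <- .find_loop(scan$loops, xyz_tags)
  if (!is.null(symloop)) {
    col <- intersect(xyz_tags, names(symloop))[1]
    xyz <- symloop[[col]]
  } else if (!is.null(items[[xyz_tags[1]]])) {
    xyz <- items[[xyz_tags[1]]]
  } else if (!is.null(items[[xyz_tags[2]]])) {
    xyz <- items[[xyz_tags[2]]]
  } else {
    key <- .sg_key(sg_name)
    known <- .known_spacegroups[vapply(names(.known_spacegroups), .sg_key, "") == key]
    if (length(known) == 1) {
      xyz <- known[[1]]
    } else {
      stop("CIF parse error: no symmetry loop and space-group name ",
           dQuote(sg_name), " is not recognized")
    }
  }
  operations <- lapply(seq_along(xyz), function(i) parse_symop_xyz(xyz[i], index = i))

  atom_loop <- .find_loop(scan$loops, "_atom_site_fract_x")
  if (is.null(atom_loop)) stop("CIF parse error: missing atom site loop")
  lbl <- if ("_atom_site_label" %in% names(atom_loop)) atom_loop[["_atom_site_label"]] else
    paste0("X", seq_len(nrow(atom_loop)))
  typ <- if ("_atom_site_type_symbol" %in% names(atom_loop)) atom_loop[["_atom_site_type_symbol"]] else lbl
  occ <- if ("_atom_site_occupancy" %in% names(atom_loop))
    .cif_number(atom_loop[["_atom_site_occupancy"]]) else rep(1, nrow(atom_loop))
  occ[is.na(occ)] <- 1
  sites <- data.frame(
    label = lbl,
    element = normalize_element(typ),
    fx = .cif_number(atom_loop[["_atom_site_fract_x"]]),
    fy = .cif_number(atom_loop[["_atom_site_fract_y"]]),
    fz = .cif_number(atom_loop[["_atom_site_fract_z"]]),
    occupancy = occ,
    stringsAsFactors = FALSE
  )
  if (anyNA(sites[c("fx", "fy", "fz")])) {
    stop("CIF parse error: non-numeric fractional coordinate in atom loop")
  }
  if (anyDuplicated(sites$label)) {
    sites$label <- make.unique(sites$label, sep = "_")
  }
  if (any(sites$occupancy < 1)) {
    warning("structure contains sites with occupancy < 1 (disorder); ",
            "downstream molecule completion refuses these by default")
  }

  structure(list(cell = cell, operations = operations, sites = sites,
                 space_group_name = trimws(sg_name), z_prime_hint = NA_integer_),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure> %s: %d symmetry ops, %d sites\n",
              if (nzchar(x$space_group_name)) x$space_group_name else "(unnamed)",
              length(x$operations), nrow(x$sites)))
  print(x$cell)
  invisible(x)
}

#' Write a crystal structure as a CSD-style CIF document
#'
#' @param structure a `crystal_structure`.
#' @param data_name the data block name.
#' @return a single string containing the CIF text.
#' @export
write_cif <- function(structure, data_name = "pixkit") {
  s <- structure
  lines <- c(
    sprintf("data_%s", data_name),
    sprintf("_symmetry_space_group_name_H-M   '%s'",
            if (nzchar(s$space_group_name)) s$space_group_name else "?"),
    sprintf("_cell_length_a     %.6f", s$cell$a),
    sprintf("_cell_length_b     %.6f", s$cell$b),
    sprintf("_cell_length_c     %.6f", s$cell$c),
    sprintf("_cell_angle_alpha  %.6f", s$cell$alpha),
    sprintf("_cell_angle_beta   %.6f", s$cell$beta),
    sprintf("_cell_angle_gamma  %.6f", s$cell$gamma),
    "loop_",
    "_symmetry_equiv_pos_site_id",
    "_symmetry_equiv_pos_as_xyz",
    vapply(s$operations, function(op)
      sprintf("%d '%s'", op$index, format_symop_xyz(op)), ""),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    sprintf("%s %s %.8f %.8f %.8f %.4f",
            s$sites$label, s$sites$element,
            s$sites$fx, s$sites$fy, s$sites$fz, s$sites$occupancy)
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Normalize a SHELXL-dialect CIF to CSD form
#'
#' Parses the document accepting SHELXL tag spellings and rewrites it with the
#' canonical CSD-style tags (`_symmetry_equiv_pos_as_xyz` symmetry loop,
#' `_symmetry_space_group_name_H-M`). A missing space-group name is recovered
#' as "P 1"/"P -1" when the operator list matches, else written as "?". The
#' transformation is idempotent.
#'
#' @param text CIF document text.
#' @param strict if `TRUE`, warnings are promoted to errors.
#' @return normalized CIF text, with a `warnings` attribute listing anything
#'   the normalizer could not fully interpret.
#' @export
normalize_shelxl_cif <- function(text, strict = FALSE) {
  warns <- character(0)
  s <- withCallingHandlers(
    parse_cif(text),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (!nzchar(s$space_group_name)) {
    ops <- vapply(s$operations, format_symop_xyz, "")
    for (nm in names(.known_spacegroups)) {
      if (setequal(ops, .known_spacegroups[[nm]])) { s$space_group_name <- nm; break }
    }
    if (!nzchar(s$space_group_name)) {
      warns <- c(warns, "space-group name missing and not recoverable from operator list")
    }
  }
  if (strict && length(warns) > 0) {
    stop("normalization warnings in strict mode: ", paste(warns, collapse = "; "))
  }
  out <- write_cif(s)
  attr(out, "warnings") <- warns
  out
}
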