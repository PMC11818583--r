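#' Parse a lipid shorthand name
#'
#' Understands MS-DIAL-style shorthand such as `"SM 36:1;2O"`,
#' `"PC O-34:2"`, `"HexCer 42:1;3O"`, `"Cer_NS 42:1;2O"` or chain-resolved
#' forms like `"PC 16:0_18:1"` / `"PC 16:0/18:1"` (chains are summed to the
#' total composition). The class token is everything before the first space;
#' subclass suffixes after an underscore (e.g. `Cer_NS`) stay part of the
#' class. Ether lipids are recognised either by an `O-`/`P-` chain prefix or
#' by an `ether` class alias (`etherPC` parses as class `PC`, ether `TRUE`).
#' The trailing `;nO` (or `;O` for one) counts additional oxygens.
#'
#' @param name character scalar, non-empty.
#' @return list with elements `lipid_class`, `ether` (logical),
#'   `total_carbons`, `double_bonds`, `oxygens` (integers), `raw_name` and
#'   `parsed` (logical; `FALSE` when no `carbons:double_bonds` field was
#'   found, in which case the numeric fields are `NA` and `lipid_class`
#'   holds the whole name).
#' @examples
#' parseLipidName("SM 36:1;2O")
#' parseLipidName("PC O-34:2")
#' parseLipidName("PC 16:0_18:1")
#' @export
parseLipidName <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  fail <- list(lipid_class = name, ether = FALSE, total_carbons = NA_integer_,
               double_bonds = NA_integer_, oxygens = NA_integer_,
               raw_name = name, parsed = FALSE)
  m <- regexec("^(\\S+)\\s+(.+)$", name)[[1]]
  if (m[1] == -1L) return(fail)
  parts <- regmatches(name, regexec("^(\\S+)\\s+(.+)$", name))[[1]]
  cls <- parts[2]; rest <- parts[3]

  ether <- FALSE
  if (grepl("^ether", cls)) {
    ether <- TRUE
    cls <- sub("^ether", "", cls)
  }

  # oxygen suffix ";nO" or ";O"
  ox <- 0L
  oxm <- regmatches(rest, regexec(";([0-9]*)O$", rest))[[1]]
  if (length(oxm)) {
    ox <- if (nzchar(oxm[2])) as.integer(oxm[2]) else 1L
    rest <- sub(";[0-9]*O$", "", rest)
  }

  if (grepl("^[OP]-", rest)) {
    ether <- TRUE
    rest <- sub("^[OP]-", "", rest)
  }

  # one or more carbon:double-bond fields separated by "_" or "/"
  chains <- strsplit(rest, "[/_]")[[1]]
  cd <- regmatches(chains, regexec("^([0-9]+):([0-9]+)$", chains))
  if (!length(chains) || any(vapply(cd, length, 1L) != 3L)) return(fail)
  carbons <- sum(vapply(cd, function(z) as.integer(z[2]), 1L))
  db      <- sum(vapply(cd, function(z) as.integer(z[3]), 1L))

  list(lipid_class = cls, ether = ether, total_carbons = carbons,
       double_bonds = db, oxygens = ox, raw_name = name, parsed = TRUE)
}

#' Format a parsed lipid annotation to canonical shorthand
#'
#' The canonical form is `"CLASS O-C:D;NO"`: class token, `O-` when ether,
#' total carbons `:` double bonds, and `;NO` only when oxygens > 0
#' (`;O` for exactly one). Chain-resolved input therefore round-trips to
#' its summed total composition.
#'
#' @param ann list as returned by [parseLipidName()].
#' @return character scalar.
#' @export
formatLipidName <- function(ann) {
  if (!isTRUE(ann$parsed)) return(ann$raw_name)
  ox <- if (ann$oxygens == 0L) "" else if (ann$oxygens == 1L) ";O" else
    sprintf(";%dO", ann$oxygens)
  sprintf("%s %s%d:%d%s", ann$lipid_class, if (ann$ether) "O-" else "",
          ann$total_carbons, ann$double_bonds, ox)
}

#' Parse a vector of lipid names into an annotation table
#'
#' @param names character vector of shorthand names.
#' @return [S4Vectors::DataFrame] with one row per name and columns
#'   `lipid_class`, `ether`, `total_carbons`, `double_bonds`, `oxygens`,
#'   `parsed`.
#' @export
annotateLipids <- function(names) {
  anns <- lapply(names, parseLipidName)
  S4Vectors::DataFrame(
    lipid_class = vapply(anns, `[[`, "", "lipid_class"),
    ether = vapply(anns, `[[`, TRUE, "ether"),
    total_carbons = vapply(anns, `[[`, 1L, "total_carbons"),
    double_bonds = vapply(anns, `[[`, 1L, "double_bonds"),
    oxygens = vapply(anns, `[[`, 1L, "oxygens"),
    parsed = vapply(anns, `[[`, TRUE, "parsed"),
    row.names = names)
}

# sphingolipid classes whose shorthand counts the d18 sphingoid backbone
.SPHINGO_CLASSES <- c("SM", "ASM", "Cer", "HexCer")

.isSphingo <- function(lipid_class) {
  base <- sub("_.*$", "", lipid_class)
  base %in% .SPHINGO_CLASSES
}
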