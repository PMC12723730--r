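# RDC tables: residue, coupling type, value (Hz), uncertainty (Hz), and the
# per-type normalization scale that brings all coupling types onto the N-H
# coupling scale before fitting.

#' Default per-type normalization scales
#'
#' Couplings of intrinsically weaker interactions are upscaled before a joint
#' fit: C'N couplings eight-fold and CaC' couplings five-fold, N-H couplings
#' unscaled.
#'
#' @return named numeric vector of scales.
#' @export
rdc_scales <- function() c("NH" = 1, "C'N" = 8, "CaC'" = 5)

#' Construct an RDC table
#'
#' @param resno integer residue numbers (for C'N couplings, the residue of
#'   the nitrogen, i.e. the second atom).
#' @param type coupling types (`"NH"`, `"C'N"`, `"CaC'"`).
#' @param value measured couplings in Hz (raw, unscaled).
#' @param uncertainty positive measurement uncertainties in Hz (raw scale).
#' @param scales named vector mapping type to normalization scale.
#' @return `rdc_table` data.frame with columns `resno`, `type`, `value`,
#'   `uncertainty`, `scale`.
#' @export
rdc_table <- function(resno, type, value, uncertainty = 1,
                      scales = rdc_scales()) {
  type <- as.character(type)
  unknown <- setdiff(unique(type), names(scales))
  if (length(unknown))
    stop("unknown coupling type(s): ", paste(unknown, collapse = ", "))
  out <- data.frame(resno = as.integer(resno), type = type,
                    value = as.numeric(value),
                    uncertainty = rep_len(as.numeric(uncertainty),
                                          length(resno)),
                    scale = unname(scales[type]),
                    stringsAsFactors = FALSE)
  if (any(out$uncertainty <= 0)) stop("uncertainties must be positive")
  dup <- duplicated(out[, c("resno", "type")])
  if (any(dup))
    stop("duplicate (residue, type) entries: ",
         paste(unique(paste0(out$resno[dup], ":", out$type[dup])),
               collapse = ", "))
  class(out) <- c("rdc_table", "data.frame")
  out
}

#' Read an RDC table from a text file
#'
#' Parses a whitespace- or comma-separated table with columns
#' residue, type, value and (optionally) uncertainty. Lines starting with
#' `#` and blank lines are ignored. Normalization scales are assigned by
#' coupling type.
#'
#' @param path file path.
#' @param default_uncertainty uncertainty (Hz) used when the fourth column
#'   is absent.
#' @param scales named vector mapping type to normalization scale; a
#'   different mapping re-scales non-default coupling types.
#' @return `rdc_table` data.frame.
#' @export
read_rdc_table <- function(path, default_uncertainty = 1,
                           scales = rdc_scales()) {
  if (!file.exists(path)) stop("cannot read RDC table: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("no data lines in ", path)
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    if (length(tok) < 3)
      stop("line ", lineno[i], ": expected residue, type, value[, uncertainty]")
    if (!tok[2] %in% names(scales))
      stop("line ", lineno[i], ": unknown coupling type '", tok[2], "'")
    val <- suppressWarnings(as.numeric(c(tok[1], tok[3],
                                         if (length(tok) >= 4) tok[4])))
    if (any(is.na(val)))
      stop("line ", lineno[i], ": non-numeric field")
    data.frame(resno = as.integer(val[1]), type = tok[2], value = val[2],
               uncertainty = if (length(val) >= 3) val[3]
                             else default_uncertainty,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rdc_table(d$resno, d$type, d$value, d$uncertainty, scales = scales)
}

# Match RDC records to bond vectors by (residue, type). Returns the matched
# rdc table and, for each conformer vector set, the aligned direction matrix.
match_rdc_vectors <- function(rdcs, vectors) {
  if (!is.list(vectors) || is.data.frame(vectors)) vectors <- list(vectors)
  keys <- lapply(vectors, function(v) paste(v$resno, v$type))
  rk <- paste(rdcs$resno, rdcs$type)
  ok <- Reduce(`&`, lapply(keys, function(k) rk %in% k))
  rdcs <- rdcs[ok, , drop = FALSE]
  rk <- rk[ok]
  if (nrow(rdcs) == 0) stop("no RDCs match the supplied bond vectors")
  dirs <- lapply(seq_along(vectors), function(j) {
    idx <- match(rk, keys[[j]])
    vector_dirs(vectors[[j]])[idx, , drop = FALSE]
  })
  list(rdcs = rdcs, dirs = dirs)
}
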