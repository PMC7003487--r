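#' Parse an IgG glycan composition string
#'
#' Compositions follow the `H<i>N<j>[F<k>][S<l>][(<arm>)]` convention used
#' for 2-AB labelled IgG N-glycans: `H` hexose (mannose/galactose), `N`
#' N-acetylglucosamine, `F` fucose, `S` N-acetylneuraminic acid. Absent
#' letters mean a count of zero. A trailing parenthesised `6` or `3` marks
#' the arm of a positional isomer (e.g. `H4N4F1(6)`) and is carried as
#' metadata only.
#'
#' @param text A single composition string, e.g. `"H3N4F1"`.
#' @return An object of class `glycan_composition`: a list with integer
#'   fields `hex`, `hexnac`, `fuc`, `neuac` and `arm` (`NA` or `"6"`/`"3"`).
#' @examples
#' parse_composition("H3N4F1")
#' parse_composition("H4N4F1(6)")
#' @export
parse_composition <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    glyconact_error("composition must be a single string", "glyconact_parse_error")
  arm <- NA_character_
  body <- text
  arm_m <- regmatches(text, regexec("^(.*)\\(([63])\\)$", text))[[1]]
  if (length(arm_m) == 3L) {
    body <- arm_m[2]
    arm <- arm_m[3]
  }
  if (grepl("\\(", body))
    glyconact_error(sprintf("malformed arm annotation in '%s'", text),
                    "glyconact_parse_error")
  tokens <- regmatches(body, gregexpr("[A-Za-z][0-9]*", body))[[1]]
  if (nchar(body) == 0L || sum(nchar(tokens)) != nchar(body))
    glyconact_error(sprintf("malformed composition '%s'", text),
                    "glyconact_parse_error")
  counts <- c(H = 0L, N = 0L, F = 0L, S = 0L)
  seen <- character(0)
  for (tok in tokens) {
    letter <- substr(tok, 1, 1)
    digits <- substr(tok, 2, nchar(tok))
    if (!letter %in% names(counts))
      glyconact_error(sprintf("unknown monosaccharide letter '%s' in '%s'",
                              letter, text), "glyconact_parse_error")
    if (letter %in% seen)
      glyconact_error(sprintf("duplicate letter '%s' in '%s'", letter, text),
                      "glyconact_parse_error")
    if (nchar(digits) == 0L)
      glyconact_error(sprintf("missing count after '%s' in '%s'", letter, text),
                      "glyconact_parse_error")
    seen <- c(seen, letter)
    counts[letter] <- as.integer(digits)
  }
  if (!all(c("H", "N") %in% seen))
    glyconact_error(sprintf("composition '%s' must name both H and N", text),
                    "glyconact_parse_error")
  structure(list(hex = counts[["H"]], hexnac = counts[["N"]],
                 fuc = counts[["F"]], neuac = counts[["S"]], arm = arm),
            class = "glycan_composition")
}

#' Format a glycan composition back to its string form
#'
#' Inverse of [parse_composition()]: zero counts for F and S are omitted,
#' the arm annotation (if any) is appended in parentheses.
#'
#' @param comp A `glycan_composition`.
#' @return A single string.
#' @export
format_composition <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  out <- sprintf("H%dN%d", comp$hex, comp$hexnac)
  if (comp$fuc > 0) out <- sprintf("%sF%d", out, comp$fuc)
  if (comp$neuac > 0) out <- sprintf("%sS%d", out, comp$neuac)
  if (!is.na(comp$arm)) out <- sprintf("%s(%s)", out, comp$arm)
  out
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition>", format_composition(x), "\n")
  invisible(x)
}

#' Derive structural features from a glycan composition
#'
#' Classification rules for the biantennary IgG panel:
#' * oligomannose: exactly the core two GlcNAc (`N == 2`); carries no
#'   galactose or fucose feature,
#' * galactose count: hexoses beyond the three core mannoses, `H - 3`,
#'   clipped to 0..2 (`NA` for oligomannose),
#' * bisecting GlcNAc: a fifth (or higher) GlcNAc (`N >= 5`),
#' * fucosylated: any fucose present,
#' * sialyl count: the NeuAc count; neutral means no NeuAc.
#'
#' @param comp A `glycan_composition` (or a composition string).
#' @return A list of class `structural_features` with fields
#'   `galactose_count` (0..2 or `NA`), `sialyl_count`, `is_fucosylated`,
#'   `is_bisecting`, `is_neutral`, `is_oligomannose`.
#' @examples
#' classify_structure("H3N4F1")  # agalactosylated, neutral, core-fucosylated
#' classify_structure("H5N2")    # oligomannose
#' @export
classify_structure <- function(comp) {
  if (is.character(comp)) comp <- parse_composition(comp)
  stopifnot(inherits(comp, "glycan_composition"))
  if (comp$hexnac < 2L)
    glyconact_error(sprintf(
      "invalid composition %s: N-glycans carry at least the core chitobiose (N >= 2)",
      format_composition(comp)), "glyconact_composition_error")
  oligo <- comp$hexnac == 2L
  structure(list(
    galactose_count = if (oligo) NA_integer_ else
      min(max(comp$hex - 3L, 0L), 2L),
    sialyl_count   = comp$neuac,
    is_fucosylated = !oligo && comp$fuc >= 1L,
    is_bisecting   = comp$hexnac >= 5L,
    is_neutral     = comp$neuac == 0L,
    is_oligomannose = oligo
  ), class = "structural_features")
}

# The 24 HILIC-UPLC peak compositions in elution order.
.panel_compositions <- c(
  GP1 = "H3N3F1", GP2 = "H3N4", GP3 = "H3N5", GP4 = "H3N4F1",
  GP5 = "H5N2", GP6 = "H3N5F1", GP7 = "H4N4", GP8 = "H4N4F1(6)",
  GP9 = "H4N4F1(3)", GP10 = "H4N5F1(6)", GP11 = "H4N5F1(3)",
  GP12 = "H5N4", GP13 = "H5N5", GP14 = "H5N4F1", GP15 = "H5N5F1",
  GP16 = "H4N4F1S1(3)", GP17 = "H5N4S1", GP18 = "H5N4F1S1",
  GP19 = "H5N5F1S1", GP20 = "H5N4F2S1", GP21 = "H5N4S2",
  GP22 = "H5N5S2", GP23 = "H5N4F1S2", GP24 = "H5N5F1S2")

#' Peak identifiers of the default 24-peak panel
#' @return Character vector `GP1` ... `GP24`.
#' @export
panel_peak_ids <- function() names(.panel_compositions)

#' The default 24-peak IgG N-glycan reference panel
#'
#' The standard HILIC-UPLC separation of 2-AB labelled serum IgG N-glycans
#' into 24 peaks, each annotated with its dominant glycan composition and
#' the structural features derived by [classify_structure()].
#'
#' @return A data.frame of class `peak_panel` with one row per peak:
#'   `peak_id`, `composition`, the monosaccharide counts (`hex`, `hexnac`,
#'   `fuc`, `neuac`, `arm`) and the feature columns (`galactose_count`,
#'   `sialyl_count`, `is_fucosylated`, `is_bisecting`, `is_neutral`,
#'   `is_oligomannose`).
#' @examples
#' panel <- default_panel()
#' subset(panel, is_bisecting)$peak_id
#' @export
default_panel <- function() {
  rows <- lapply(names(.panel_compositions), function(id) {
    comp <- parse_composition(.panel_compositions[[id]])
    feat <- classify_structure(comp)
    data.frame(peak_id = id, composition = .panel_compositions[[id]],
               hex = comp$hex, hexnac = comp$hexnac, fuc = comp$fuc,
               neuac = comp$neuac, arm = comp$arm,
               galactose_count = feat$galactose_count,
               sialyl_count = feat$sialyl_count,
               is_fucosylated = feat$is_fucosylated,
               is_bisecting = feat$is_bisecting,
               is_neutral = feat$is_neutral,
               is_oligomannose = feat$is_oligomannose,
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  rownames(panel) <- panel$peak_id
  class(panel) <- c("peak_panel", "data.frame")
  attr(panel, "panel_name") <- "igg-hilic-uplc-24"
  panel
}

#' Write / read a peak panel as CSV
#'
#' Serializes `peak_id`, `composition` and the derived feature columns.
#' On read, features are re-derived from the composition (they are a pure
#' function of it), so a hand-edited CSV cannot carry inconsistent features.
#'
#' @param panel A `peak_panel`.
#' @param path File path.
#' @return `read_panel_csv` returns a `peak_panel`.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("peak_id", "composition") %in% names(raw)))
    glyconact_error("panel CSV needs columns peak_id and composition",
                    "glyconact_schema_error")
  if (anyDuplicated(raw$peak_id))
    glyconact_error("panel CSV has duplicated peak_id values",
                    "glyconact_schema_error")
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    comp <- parse_composition(raw$composition[i])
    feat <- classify_structure(comp)
    data.frame(peak_id = raw$peak_id[i], composition = raw$composition[i],
               hex = comp$hex, hexnac = comp$hexnac, fuc = comp$fuc,
               neuac = comp$neuac, arm = comp$arm,
               galactose_count = feat$galactose_count,
               sialyl_count = feat$sialyl_count,
               is_fucosylated = feat$is_fucosylated,
               is_bisecting = feat$is_bisecting,
               is_neutral = feat$is_neutral,
               is_oligomannose = feat$is_oligomannose,
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  rownames(panel) <- panel$peak_id
  class(panel) <- c("peak_panel", "data.frame")
  panel
}
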