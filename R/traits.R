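#' The default 17 summarized IgG glycan traits
#'
#' Summarized traits over the 24-peak panel, grouped by structural feature.
#' Linear-sum traits (percent of total IgG glycans): `GPN` (neutral glycans,
#' GP1-GP15), `S1_total`/`S2_total`/`S_total` (mono-/di-/total sialylation;
#' the difucosylated monosialylated GP20 is excluded from these sums),
#' `G0_total`/`G1_total`/`G2_total` (a-/mono-/di-galactosylation),
#' `F_total` (fucosylation), `B_total` (bisecting GlcNAc). Ratio traits:
#' `F_neutral` and `B_neutral` (percent of neutral glycans), `F_sialo` and
#' `B_sialo` (percent of sialylated glycans GP16-GP24), the galactosylation
#' distribution of fucosylated glycans `FG0`/`FG1`/`FG2` (fractions of total
#' fucosylated glycans, summing to 1), and the `Gal_ratio`
#' `FG0 / (FG1 + 2 * FG2)`, which weights digalactosylated structures twice.
#'
#' Each definition is a list with `name`, `kind` (`"linear-sum"` or
#' `"ratio"`), `numerator` (named weights over peak ids), `denominator`
#' (named weights, ratio kind only) and `scale`.
#'
#' @param panel A `peak_panel` (default [default_panel()]).
#' @return Named list of 17 trait definitions.
#' @export
default_trait_set <- function(panel = default_panel()) {
  ids <- panel$peak_id
  w <- function(ids, weight = 1) stats::setNames(rep(weight, length(ids)), ids)
  pick <- function(cond) ids[which(cond)]  # which() drops NA (oligomannose)

  neutral <- pick(panel$is_neutral & !panel$is_oligomannose)
  sialylated <- pick(panel$sialyl_count > 0)
  fuc <- pick(panel$is_fucosylated)
  bis <- pick(panel$is_bisecting)
  g0 <- pick(!panel$is_oligomannose & panel$is_neutral & panel$galactose_count == 0)
  g1 <- pick(!panel$is_oligomannose & panel$is_neutral & panel$galactose_count == 1)
  g2 <- pick(!panel$is_oligomannose & panel$is_neutral & panel$galactose_count == 2)
  gpn <- pick(panel$is_neutral)                      # includes oligomannose GP5
  # Mono-/disialylated sums follow the reference convention of excluding the
  # difucosylated GP20 from the sialylation totals (it stays in the
  # sialylated denominator of the *_sialo ratios and in FG2).
  s1 <- setdiff(pick(panel$sialyl_count == 1), "GP20")
  s2 <- pick(panel$sialyl_count == 2)
  fg0 <- intersect(fuc, g0)
  fg1 <- intersect(fuc, union(g1, pick(panel$sialyl_count >= 1 &
                                         panel$galactose_count == 1)))
  fg2 <- intersect(fuc, union(g2, pick(panel$sialyl_count >= 1 &
                                         panel$galactose_count == 2)))

  lin <- function(name, peaks)
    list(name = name, kind = "linear-sum", numerator = w(peaks),
         denominator = NULL, scale = 1)
  rat <- function(name, num, den, scale = 1)
    list(name = name, kind = "ratio", numerator = num, denominator = den,
         scale = scale)

  defs <- list(
    lin("GPN", gpn),
    lin("S1_total", s1),
    lin("S2_total", s2),
    lin("S_total", c(s1, s2)),
    lin("G0_total", g0),
    lin("G1_total", g1),
    lin("G2_total", g2),
    lin("F_total", fuc),
    rat("F_neutral", w(intersect(fuc, neutral)), w(gpn), scale = 100),
    rat("F_sialo", w(intersect(fuc, sialylated)), w(sialylated), scale = 100),
    lin("B_total", bis),
    rat("B_neutral", w(intersect(bis, neutral)), w(gpn), scale = 100),
    rat("B_sialo", w(intersect(bis, sialylated)), w(sialylated), scale = 100),
    rat("Gal_ratio", w(fg0), c(w(fg1, 1), w(fg2, 2))),
    rat("FG0", w(fg0), w(fuc)),
    rat("FG1", w(fg1), w(fuc)),
    rat("FG2", w(fg2), w(fuc))
  )
  stats::setNames(defs, vapply(defs, `[[`, character(1), "name"))
}

#' Trait names of the default trait set
#' @return Character vector of the 17 trait names.
#' @export
trait_names <- function() names(default_trait_set())

#' Compute summarized glycan traits per sample
#'
#' Evaluates each trait definition on normalized profiles (percent scale).
#' Linear-sum traits are weighted sums of member peak abundances; ratio
#' traits divide two weighted sums. A ratio trait whose denominator is zero
#' for a sample is undefined: its value is `NA` and a
#' `glyconact_undefined_trait` warning names the trait, never a silent 0.
#'
#' @param profiles A data.frame with `sample_id` and the panel peak columns
#'   (percent), or a named numeric vector for one sample.
#' @param defs Trait definitions (default [default_trait_set()]).
#' @return A data.frame: `sample_id` plus one column per trait (a named
#'   vector if a vector was supplied).
#' @examples
#' prof <- stats::setNames(rep(100 / 24, 24), panel_peak_ids())
#' compute_traits(prof)[["G0_total"]]
#' @export
compute_traits <- function(profiles, defs = default_trait_set()) {
  vector_in <- is.numeric(profiles) && !is.data.frame(profiles)
  if (vector_in) {
    profiles <- cbind(data.frame(sample_id = "sample"),
                      as.data.frame(as.list(profiles)))
  }
  peak_ids <- unique(unlist(lapply(defs, function(d)
    c(names(d$numerator), names(d$denominator)))))
  check_profile_columns(profiles, peak_ids)
  m <- as.matrix(profiles[, panel_peak_ids()[panel_peak_ids() %in%
                                               names(profiles)], drop = FALSE])

  weight_vec <- function(wts) {
    v <- stats::setNames(numeric(ncol(m)), colnames(m))
    v[names(wts)] <- wts
    v
  }
  out <- data.frame(sample_id = profiles$sample_id, stringsAsFactors = FALSE)
  undefined <- character(0)
  for (d in defs) {
    num <- as.numeric(m %*% weight_vec(d$numerator))
    if (identical(d$kind, "linear-sum")) {
      out[[d$name]] <- d$scale * num
    } else {
      den <- as.numeric(m %*% weight_vec(d$denominator))
      val <- ifelse(den > 0, d$scale * num / den, NA_real_)
      if (any(den <= 0)) undefined <- c(undefined, d$name)
      out[[d$name]] <- val
    }
  }
  if (length(undefined))
    glyconact_warning(sprintf(
      "trait(s) undefined (zero denominator) for some samples: %s",
      paste(unique(undefined), collapse = ", ")),
      "glyconact_undefined_trait")
  if (vector_in) {
    v <- unlist(out[1, -1])
    return(v)
  }
  out
}

#' Write / read trait definitions as JSON
#'
#' Users may supply an alternative trait-definition file; definitions are
#' data, not code. The JSON is a list of objects with fields `name`, `kind`,
#' `numerator`, `denominator` (omitted for linear sums) and `scale`.
#'
#' @param defs Trait definitions.
#' @param path File path.
#' @return `read_trait_definitions` returns the definitions list.
#' @export
write_trait_definitions <- function(defs, path) {
  out <- lapply(unname(defs), function(d) {
    x <- list(name = d$name, kind = d$kind,
              numerator = as.list(d$numerator), scale = d$scale)
    if (!is.null(d$denominator)) x$denominator <- as.list(d$denominator)
    x
  })
  write_json_atomic(out, path)
  invisible(path)
}

#' @rdname write_trait_definitions
#' @export
read_trait_definitions <- function(path) {
  raw <- jsonlite::read_json(path)
  defs <- lapply(raw, function(x) {
    if (is.null(x$name) || is.null(x$kind) || is.null(x$numerator))
      glyconact_error("trait definition needs name, kind and numerator",
                      "glyconact_schema_error")
    if (!x$kind %in% c("linear-sum", "ratio"))
      glyconact_error(sprintf("unknown trait kind '%s'", x$kind),
                      "glyconact_schema_error")
    if (identical(x$kind, "ratio") && is.null(x$denominator))
      glyconact_error(sprintf("ratio trait '%s' needs a denominator", x$name),
                      "glyconact_schema_error")
    list(name = x$name, kind = x$kind,
         numerator = unlist(x$numerator),
         denominator = if (!is.null(x$denominator)) unlist(x$denominator),
         scale = if (!is.null(x$scale)) as.numeric(x$scale) else 1)
  })
  stats::setNames(defs, vapply(defs, `[[`, character(1), "name"))
}
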