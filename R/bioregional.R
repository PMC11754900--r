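#' Standard bioregion abbreviations
#'
#' Abbreviations for the Antarctic Conservation Biogeographic Regions
#' used in Tier 3 codes; the synthetic generator draws its bioregion
#' names from this list.
#'
#' @return Character vector of abbreviations.
#' @export
acbr_abbreviations <- function() {
  c("NEAP", "NWAP", "CSAP", "EDL", "DML", "EA", "NVL", "SVL", "TM",
    "EM", "MBL", "AL", "EWL", "SAP", "PCM")
}

#' Format a Tier 3 ecosystem code
#'
#' Combines the Habitat Complex code string with the bioregion
#' abbreviation, e.g. `E2B1-NWAP`. Overlay Major Environmental Units
#' carry a single Habitat Complex, so their codes omit a `B` part
#' (`L1-EA`, `G2-SVL`). Amalgamated units append `a`.
#'
#' @param tier1 Major Environmental Unit code (`"E2"`, `"G1"`, `"L1"`).
#' @param tier2 Habitat Complex part (`"B1"`), or `""`/`NULL` for
#'   overlay units.
#' @param bioregion_abbrev Bioregion abbreviation (validated against
#'   `known_abbrevs`).
#' @param amalgamated Append the amalgamation suffix?
#' @param known_abbrevs Abbreviation whitelist, default
#'   [acbr_abbreviations()].
#' @return The code string.
#' @export
format_code <- function(tier1, tier2, bioregion_abbrev,
                        amalgamated = FALSE,
                        known_abbrevs = acbr_abbreviations()) {
  if (!bioregion_abbrev %in% known_abbrevs)
    stop("unknown bioregion abbreviation: ", bioregion_abbrev)
  if (is.null(tier2)) tier2 <- ""
  paste0(tier1, tier2, "-", bioregion_abbrev,
         if (isTRUE(amalgamated)) "a" else "")
}

#' Intersect Habitat Complexes with bioregions
#'
#' One candidate Tier 3 unit is created for every nonempty combination
#' of Habitat Complex and bioregion; combinations that do not occur are
#' absent. Pixel counts are conserved.
#'
#' @param tier2_labels A [label_grid()] of Habitat Complexes (legend
#'   labels like `E2B1`, `G1`, `L1`).
#' @param bioregions A [label_grid()] of bioregions whose legend holds
#'   the abbreviations.
#' @param units Optional data frame mapping tier2 `code` to `tier1` and
#'   `tier2` strings (as produced by [classify_tier2()] /
#'   [assemble_overlays()]); derived from legend labels when absent.
#' @param known_abbrevs Abbreviation whitelist for [format_code()].
#' @return List with `labels` (candidate [label_grid()]) and `units`
#'   (the candidate unit table).
#' @export
intersect_bioregions <- function(tier2_labels, bioregions, units = NULL,
                                 known_abbrevs = acbr_abbreviations()) {
  stopifnot_same_grid(tier2_labels$grid, bioregions$grid)
  grid <- tier2_labels$grid
  t2 <- tier2_labels$codes
  br <- bioregions$codes
  if (is.null(units)) units <- units_from_legend(tier2_labels$legend)

  sel <- t2 > 0L & br > 0L
  combo_key <- paste(t2[sel], br[sel])
  tab <- table(combo_key)
  keys <- names(tab)
  parts <- do.call(rbind, strsplit(keys, " "))
  t2_codes <- as.integer(parts[, 1])
  br_codes <- as.integer(parts[, 2])
  # deterministic candidate order: by tier2 code then bioregion code
  ord <- order(t2_codes, br_codes)
  t2_codes <- t2_codes[ord]; br_codes <- br_codes[ord]
  counts <- as.integer(tab)[ord]

  rows <- lapply(seq_along(t2_codes), function(i) {
    u <- units[units$code == t2_codes[i], ]
    ab <- unname(bioregions$legend[as.character(br_codes[i])])
    data.frame(
      tier3_code = i,
      code = format_code(u$tier1, u$tier2, ab,
                         known_abbrevs = known_abbrevs),
      tier2_code = t2_codes[i], tier2 = u$label, tier1 = u$tier1,
      bioregion_abbrev = ab, pixel_count = counts[i],
      amalgamated = FALSE, absorbed_from = "",
      stringsAsFactors = FALSE)
  })
  unit_table <- do.call(rbind, rows)

  lut <- integer(max(t2) * 0L)
  codes <- matrix(0L, grid$nrows, grid$ncols)
  key_to_id <- stats::setNames(unit_table$tier3_code,
                               paste(t2_codes, br_codes))
  codes[sel] <- unname(key_to_id[combo_key])
  labels <- label_grid(grid, codes,
                       legend = stats::setNames(unit_table$code,
                                                unit_table$tier3_code))
  list(labels = labels, units = unit_table)
}

units_from_legend <- function(legend) {
  labs <- unname(legend)
  t1 <- sub("^((E\\d+)|(G\\d+)|(L\\d+)).*$", "\\1", labs)
  t2 <- sub("^(E\\d+|G\\d+|L\\d+)", "", labs)
  data.frame(code = as.integer(names(legend)), label = labs,
             tier1 = t1, tier2 = t2, stringsAsFactors = FALSE)
}

#' Amalgamate marginal Tier 3 fragments
#'
#' Applies the decision rules for lumping candidate bioregional units:
#' candidates smaller than `min_pixels` are processed in ascending size
#' order; each is merged into an adjacent unit of the same Major
#' Environmental Unit when at least `adjacency_threshold` of its pixels
#' border that unit (see [adjacency_fractions()]). Among qualifying
#' neighbours the one with the largest adjacency fraction wins (ties:
#' larger neighbour, then lower code). The absorbing unit's code gains
#' the suffix `a`. Units with no qualifying neighbour are retained with
#' a logged reason. The pass repeats until no further merge applies, so
#' a second call changes nothing and pixel counts are conserved.
#'
#' @param candidates Output of [intersect_bioregions()] (list with
#'   `labels` and `units`).
#' @param min_pixels Minimum viable unit size in pixels (default 100 =
#'   1 km^2 at 100 m resolution).
#' @param adjacency_threshold Fraction of pixels that must border a
#'   neighbour for adjacency, default 0.05.
#' @param connectivity 4 or 8 (default).
#' @return List with `labels` (final [label_grid()]), `units` (final
#'   unit table), and `log` (data frame of merge/retain decisions).
#' @export
amalgamate <- function(candidates, min_pixels = 100,
                       adjacency_threshold = 0.05, connectivity = 8) {
  labels <- candidates$labels
  units <- candidates$units
  grid <- labels$grid
  codes <- labels$codes
  log <- list()

  repeat {
    counts <- table(factor(codes[codes > 0L],
                           levels = units$tier3_code))
    units$pixel_count <- as.integer(counts[as.character(units$tier3_code)])
    small <- units[units$pixel_count > 0L &
                     units$pixel_count < min_pixels, ]
    if (!nrow(small)) break
    small <- small[order(small$pixel_count, small$tier3_code), ]
    merged_any <- FALSE
    for (i in seq_len(nrow(small))) {
      uc <- small$tier3_code[i]
      if (!any(codes == uc)) next   # absorbed earlier this pass
      fr <- adjacency_fractions(label_grid(grid, codes), uc,
                                connectivity = connectivity)
      if (length(fr)) {
        nb_codes <- as.integer(names(fr))
        nb <- units[match(nb_codes, units$tier3_code), ]
        qual <- fr >= adjacency_threshold & nb$tier1 == small$tier1[i]
        if (any(qual)) {
          cand <- data.frame(code = nb_codes[qual], frac = fr[qual],
                             size = nb$pixel_count[qual])
          cand <- cand[order(-cand$frac, -cand$size, cand$code), ]
          target <- cand$code[1]
          codes[codes == uc] <- target
          ti <- match(target, units$tier3_code)
          units$amalgamated[ti] <- TRUE
          units$absorbed_from[ti] <- paste(
            c(strsplit(units$absorbed_from[ti], ";")[[1]],
              units$code[match(uc, units$tier3_code)]), collapse = ";")
          log[[length(log) + 1L]] <- data.frame(
            unit = units$code[match(uc, units$tier3_code)],
            action = "merged",
            into = units$code[ti], stringsAsFactors = FALSE)
          merged_any <- TRUE
          next
        }
      }
      log[[length(log) + 1L]] <- data.frame(
        unit = units$code[match(uc, units$tier3_code)],
        action = "retained-small", into = NA_character_,
        stringsAsFactors = FALSE)
    }
    if (!merged_any) break
  }

  counts <- table(factor(codes[codes > 0L], levels = units$tier3_code))
  units$pixel_count <- as.integer(counts[as.character(units$tier3_code)])
  units <- units[units$pixel_count > 0L, , drop = FALSE]
  units$code <- ifelse(units$amalgamated & !grepl("a$", units$code),
                       paste0(units$code, "a"), units$code)
  legend <- stats::setNames(units$code, units$tier3_code)
  list(labels = label_grid(grid, codes, legend = legend),
       units = units,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(unit = character(), action = character(),
                    into = character()))
}
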