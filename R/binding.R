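#' Select one reference TSS per gene
#'
#' Among each gene's candidate transcription start sites, picks the one with
#' the highest CAGE score; when several candidates tie at the maximum, the
#' reference position is the midpoint of the tied positions (rounded down).
#' Strand is carried through. Candidates for one gene on more than one
#' chromosome are a consistency error.
#'
#' @param candidates Tibble with columns `gene`, `chrom`, `strand`,
#'   `position`, `cage_score` (>= 1 row per gene).
#' @return Tibble with one row per gene: `gene`, `chrom`, `strand`,
#'   `position`, `cage_score`.
#' @examples
#' select_reference_tss(tibble::tibble(
#'   gene = "g", chrom = "chr1", strand = "+",
#'   position = c(100, 400, 900), cage_score = c(5, 9, 2)))
#' @export
select_reference_tss <- function(candidates) {
  candidates <- as_tibble(candidates)
  bad <- candidates %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(nc = dplyr::n_distinct(.data$chrom)) %>%
    dplyr::filter(.data$nc > 1)
  if (nrow(bad) > 0) {
    abort(paste0("candidate TSSs on multiple chromosomes for gene(s): ",
                 paste(head(bad$gene, 5), collapse = ", ")),
          class = "kdbind_consistency_error")
  }
  candidates %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[which.max(.data$cage_score)],
      position = {
        top <- .data$position[.data$cage_score == max(.data$cage_score)]
        if (length(top) == 1) top else floor((min(top) + max(top)) / 2)
      },
      cage_score = max(.data$cage_score)
    ) %>%
    dplyr::ungroup()
}

#' Build per-factor binding maps from peaks and footprint sites
#'
#' Footprint-style (DNase) sites are filtered to posterior strictly greater
#' than `posterior_threshold`; the per-factor union of all records is taken;
#' each interval `[start, end)` is reduced to its midpoint
#' `floor((start + end) / 2)`; and duplicates are removed on
#' `(factor, chrom, midpoint)`. Records that already carry a `midpoint`
#' column are used as-is, which makes the operation idempotent.
#'
#' @param chip_peaks Tibble of ChIP-style records: `factor`, `chrom`,
#'   `start`, `end` (0-based half-open), or NULL.
#' @param dnase_sites Tibble of footprint records: as above plus `posterior`,
#'   `motif_score`, `cons_score`, or NULL.
#' @param posterior_threshold Strict lower bound on the footprint posterior
#'   (default 0.95).
#' @return Tibble: `factor`, `chrom`, `midpoint`, `source`, `posterior`,
#'   `motif_score`, `cons_score`. Factors with no surviving records simply
#'   have no rows.
#' @export
unify_binding_events <- function(chip_peaks = NULL, dnase_sites = NULL,
                                 posterior_threshold = 0.95) {
  norm <- function(x, default_source) {
    if (is.null(x) || nrow(x) == 0) return(NULL)
    x <- as_tibble(x)
    if (!"midpoint" %in% names(x)) {
      if (any(x$end <= x$start)) {
        abort("malformed interval: end <= start",
              class = "kdbind_parse_error")
      }
      x$midpoint <- floor((x$start + x$end) / 2)
    }
    if (!"source" %in% names(x)) x$source <- default_source
    for (col in c("posterior", "motif_score", "cons_score")) {
      if (!col %in% names(x)) x[[col]] <- NA_real_
    }
    dplyr::select(x, "factor", "chrom", "midpoint", "source", "posterior",
                  "motif_score", "cons_score")
  }
  ev <- dplyr::bind_rows(norm(chip_peaks, "chip"), norm(dnase_sites, "dnase"))
  if (is.null(ev) || nrow(ev) == 0) {
    return(tibble(factor = character(), chrom = character(),
                  midpoint = integer(), source = character(),
                  posterior = double(), motif_score = double(),
                  cons_score = double()))
  }
  ev %>%
    dplyr::filter(.data$source != "dnase" |
                    (!is.na(.data$posterior) &
                       .data$posterior > posterior_threshold)) %>%
    dplyr::distinct(.data$factor, .data$chrom, .data$midpoint,
                    .keep_all = TRUE)
}

#' Assign binding events to genes by a TSS window
#'
#' An event is assigned to a gene when it lies on the same chromosome and
#' its absolute distance to the gene's reference TSS is at most `window`
#' (inclusive). A positive `inner` radius excludes promoter-proximal events:
#' only events with distance strictly greater than `inner` are kept (the
#' promoter-excluded annulus).
#'
#' @param events Unified binding events ([unify_binding_events()]).
#' @param tss Reference TSS table ([select_reference_tss()]).
#' @param window Window half-width in bp (> 0).
#' @param inner Inner exclusion radius in bp (default 0 = none).
#' @return A tibble of class `kd_assignment`, one row per (event, gene)
#'   pair: `gene`, `factor`, `chrom`, `midpoint`, `distance`, `source`,
#'   `posterior`, `motif_score`, `cons_score`; attributes `window`, `inner`.
#' @export
assign_targets_window <- function(events, tss, window = 10000, inner = 0) {
  if (!is.numeric(window) || window <= 0) {
    abort("`window` must be positive", class = "kdbind_config_error")
  }
  events <- as_tibble(events)
  tss <- as_tibble(tss)
  pairs <- purrr::map_dfr(intersect(unique(events$chrom), unique(tss$chrom)),
    function(ch) {
      ev <- events[events$chrom == ch, ]
      ts <- tss[tss$chrom == ch, ]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(ev$midpoint, ev$midpoint),
        IRanges::IRanges(ts$position - window, ts$position + window)
      )
      i <- S4Vectors::queryHits(hits)
      j <- S4Vectors::subjectHits(hits)
      dplyr::bind_cols(
        tibble(gene = ts$gene[j]),
        ev[i, c("factor", "chrom", "midpoint", "source", "posterior",
                "motif_score", "cons_score")],
        tibble(distance = abs(ev$midpoint[i] - ts$position[j]))
      )
    })
  if (inner > 0 && nrow(pairs) > 0) {
    pairs <- pairs[pairs$distance > inner, ]
  }
  structure(dplyr::select(pairs, "gene", "factor", "chrom", "midpoint",
                          "distance", "source", "posterior", "motif_score",
                          "cons_score"),
            class = c("kd_assignment", class(tibble())),
            window = window, inner = inner)
}

#' Assign binding events to genes through distal-element links
#'
#' An event is assigned to gene `g` when its midpoint falls inside a
#' regulatory element (0-based half-open interval) linked to `g`; an element
#' linked to several genes assigns the event to each of them.
#'
#' @param events Unified binding events.
#' @param links Tibble: `chrom`, `start`, `end`, `gene`, `score`.
#' @param tss Optional reference TSS table used to attach TSS distances.
#' @return A `kd_assignment` tibble as in [assign_targets_window()]
#'   (`distance` is NA unless `tss` is given).
#' @export
assign_targets_distal <- function(events, links, tss = NULL) {
  events <- as_tibble(events)
  links <- as_tibble(links)
  if (any(links$end <= links$start)) {
    abort("malformed link interval: end <= start",
          class = "kdbind_parse_error")
  }
  pairs <- purrr::map_dfr(intersect(unique(events$chrom),
                                    unique(links$chrom)),
    function(ch) {
      ev <- events[events$chrom == ch, ]
      ln <- links[links$chrom == ch, ]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(ev$midpoint + 1L, ev$midpoint + 1L),
        IRanges::IRanges(ln$start + 1L, ln$end)
      )
      i <- S4Vectors::queryHits(hits)
      j <- S4Vectors::subjectHits(hits)
      dplyr::bind_cols(
        tibble(gene = ln$gene[j]),
        ev[i, c("factor", "chrom", "midpoint", "source", "posterior",
                "motif_score", "cons_score")]
      )
    })
  if (nrow(pairs) == 0) {
    pairs <- tibble(gene = character(), factor = character(),
                    chrom = character(), midpoint = integer(),
                    source = character(), posterior = double(),
                    motif_score = double(), cons_score = double())
  }
  pairs$distance <- NA_real_
  if (!is.null(tss) && nrow(pairs) > 0) {
    pos <- setNames(tss$position, tss$gene)
    pairs$distance <- abs(pairs$midpoint - unname(pos[pairs$gene]))
  }
  structure(dplyr::select(pairs, "gene", "factor", "chrom", "midpoint",
                          "distance", "source", "posterior", "motif_score",
                          "cons_score"),
            class = c("kd_assignment", class(tibble())),
            window = NA_real_, inner = 0)
}

#' Per-(gene, factor) binding-event counts
#'
#' @param assignment A `kd_assignment` tibble.
#' @return Tibble `gene`, `factor`, `n` (sparse: only nonzero counts).
#' @export
target_counts <- function(assignment) {
  dplyr::count(as_tibble(assignment), .data$gene, .data$factor, name = "n")
}

#' Label binding events with the chromatin state containing them
#'
#' Chromatin-state segments are 0-based half-open and tile the chromosome; a
#' midpoint equal to a segment's start belongs to that segment, one equal to
#' its end belongs to the next. Events outside all segments are labelled
#' "unannotated" with a message.
#'
#' @param events Tibble with `chrom` and `midpoint` (unified events or an
#'   assignment).
#' @param states Tibble: `chrom`, `start`, `end`, `state`.
#' @return The input with a `state` column appended.
#' @export
annotate_site_state <- function(events, states) {
  events <- as_tibble(events)
  states <- as_tibble(states)
  out <- rep(NA_character_, nrow(events))
  for (ch in unique(events$chrom)) {
    ei <- which(events$chrom == ch)
    st <- states[states$chrom == ch, ]
    st <- st[order(st$start), ]
    if (nrow(st) == 0) next
    idx <- findInterval(events$midpoint[ei], st$start)
    ok <- idx >= 1 & idx <= nrow(st)
    ok[ok] <- events$midpoint[ei][ok] < st$end[idx[ok]]
    out[ei[ok]] <- st$state[idx[ok]]
  }
  n_un <- sum(is.na(out))
  if (n_un > 0) {
    inform(sprintf("annotate_site_state: %d event(s) outside all segments",
                   n_un))
    out[is.na(out)] <- "unannotated"
  }
  events$state <- out
  events
}

#' Distances from binding events to their assigned TSS
#'
#' Attaches a log-transformed distance: on the default kb scale,
#' `log10(distance_kb + 0.001)` (an event at the TSS maps to -3); with
#' `scale = "bp"`, `log10(distance_bp + 0.001)`.
#'
#' @param assignment A `kd_assignment` with a `distance` column (bp).
#' @param scale `"kb"` (default) or `"bp"`.
#' @return The assignment with a `log_distance` column appended.
#' @export
site_distance_to_tss <- function(assignment, scale = c("kb", "bp")) {
  scale <- match.arg(scale)
  d <- assignment$distance
  assignment$log_distance <- switch(scale,
    kb = log10(d / 1000 + 0.001),
    bp = log10(d + 0.001)
  )
  assignment
}
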