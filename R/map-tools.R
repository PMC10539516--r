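#' Construct a linkage map
#'
#' A linkage map is a data.frame of markers with columns `lg`, `marker_id`,
#' `radtag_id`, `pos_cM`, ordered by position within each linkage group,
#' with positions anchored so each LG starts at 0.
#'
#' @param df data.frame with columns `lg`, `marker_id`, `radtag_id`,
#'   `pos_cM`.
#' @param sex_label `"male"`, `"female"` or `"averaged"`.
#' @param anchor shift each LG so its minimum position is 0 (default TRUE).
#' @return data.frame of class `linkage_map` with attribute `sex_label`.
#' @export
linkage_map <- function(df, sex_label = c("averaged", "male", "female"),
                        anchor = TRUE) {
  sex_label <- match.arg(sex_label)
  req <- c("lg", "marker_id", "radtag_id", "pos_cM")
  if (!all(req %in% names(df))) {
    stop("linkage map needs columns: ", paste(req, collapse = ", "))
  }
  df <- as.data.frame(df)[, req]
  if (anyDuplicated(df$marker_id)) stop("duplicated marker_id in map")
  if (any(df$pos_cM < 0)) stop("negative map positions")
  df <- df[order(df$lg, df$pos_cM, df$marker_id), , drop = FALSE]
  if (anchor && nrow(df)) {
    df$pos_cM <- df$pos_cM - stats::ave(df$pos_cM, df$lg, FUN = min)
  }
  rownames(df) <- NULL
  structure(df, class = c("linkage_map", "data.frame"), sex_label = sex_label)
}

#' Read / write a linkage map TSV
#'
#' The exchange format is a TSV with header
#' `lg  marker_id  radtag_id  pos_cM`.
#'
#' @param path file path.
#' @param sex_label map label for [linkage_map].
#' @return a `linkage_map`.
#' @export
read_linkage_map <- function(path, sex_label = "averaged") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(lg = "character",
                                         marker_id = "character",
                                         radtag_id = "character",
                                         pos_cM = "numeric"))
  linkage_map(df, sex_label, anchor = FALSE)
}

#' @rdname read_linkage_map
#' @param map a `linkage_map`.
#' @export
write_linkage_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Clean a linkage map
#'
#' Applies two error-screening rules: (a) any RADtag whose markers occur on
#' more than one linkage group is removed entirely (a biological
#' impossibility, hence a genotyping artifact); (b) iteratively, whenever
#' the markers of a single RADtag occupy a terminal segment of an LG
#' separated from the rest by a gap larger than `gap_threshold_cM`, that
#' RADtag is removed. Positions are re-anchored to 0 after removals. The
#' operation is idempotent and never increases an LG length.
#'
#' @param map a [linkage_map].
#' @param gap_threshold_cM terminal-gap threshold (default 10; strict).
#' @return list with `map` (cleaned) and `removed` (data.frame
#'   `radtag_id`, `reason`).
#' @export
clean_map <- function(map, gap_threshold_cM = 10) {
  sex_label <- attr(map, "sex_label")
  if (is.null(sex_label)) sex_label <- "averaged"
  removed <- data.frame(radtag_id = character(), reason = character())
  tags_lgs <- unique(as.data.frame(map)[, c("radtag_id", "lg")])
  multi <- unique(tags_lgs$radtag_id[duplicated(tags_lgs$radtag_id)])
  if (length(multi)) {
    removed <- rbind(removed, data.frame(radtag_id = multi,
                                         reason = "multiple_lgs"))
    map <- map[!map$radtag_id %in% multi, , drop = FALSE]
  }
  repeat {
    dropped <- character(0)
    for (lg in unique(map$lg)) {
      sub <- map[map$lg == lg, , drop = FALSE]
      sub <- sub[order(sub$pos_cM), , drop = FALSE]
      gaps <- diff(sub$pos_cM)
      for (end in c("tail", "head")) {
        if (nrow(sub) < 2L) break
        big <- which(gaps > gap_threshold_cM)
        if (!length(big)) next
        if (end == "tail") {
          seg <- (max(big) + 1L):nrow(sub)
        } else {
          seg <- 1L:min(big)
        }
        seg_tags <- unique(sub$radtag_id[seg])
        if (length(seg_tags) == 1L) {
          dropped <- c(dropped, seg_tags)
          sub <- sub[-seg, , drop = FALSE]
          gaps <- diff(sub$pos_cM)
        }
      }
    }
    if (!length(dropped)) break
    removed <- rbind(removed, data.frame(radtag_id = unique(dropped),
                                         reason = "terminal_gap"))
    map <- map[!map$radtag_id %in% dropped, , drop = FALSE]
  }
  map <- linkage_map(as.data.frame(map), sex_label)
  list(map = map, removed = removed)
}

#' Merge male and female maps into a sex-averaged map
#'
#' Markers present on both maps (the double-heterozygous anchors) are placed
#' at the arithmetic mean of their two positions,
#' `(male position + female position) / 2`. Markers present on only one map
#' are carried over by piecewise-linear interpolation of their source-map
#' coordinate between the flanking shared anchors (terminal markers by
#' linear extrapolation from the two nearest anchors). An LG with fewer than
#' two shared anchors passes through from the female map (the denser, more
#' evenly spread of the two) with a warning. Each LG is re-sorted by
#' averaged position and re-anchored to start at 0.
#'
#' @param male_map,female_map `linkage_map`s with matching LG labels.
#' @return the sex-averaged [linkage_map].
#' @export
merge_sex_maps <- function(male_map, female_map) {
  lgs <- union(unique(male_map$lg), unique(female_map$lg))
  pieces <- list()
  for (lg in lgs) {
    mm <- male_map[male_map$lg == lg, , drop = FALSE]
    fm <- female_map[female_map$lg == lg, , drop = FALSE]
    shared <- intersect(mm$marker_id, fm$marker_id)
    if (length(shared) < 2L) {
      warning("LG ", lg, ": fewer than 2 shared markers; ",
              "passing the female map through")
      pieces[[lg]] <- fm
      next
    }
    mpos <- mm$pos_cM[match(shared, mm$marker_id)]
    fpos <- fm$pos_cM[match(shared, fm$marker_id)]
    avg <- (mpos + fpos) / 2

    interp <- function(src_pos, anchors_src, anchors_avg) {
      o <- order(anchors_src)
      stats::approx(anchors_src[o], anchors_avg[o], xout = src_pos,
                    rule = 2, ties = mean)$y +
        extrapolate_tail(src_pos, anchors_src[o], anchors_avg[o])
    }
    # approx(rule = 2) clamps beyond the range; add the linear extrapolation
    # from the two nearest anchors for out-of-range markers.
    extrapolate_tail <- function(src_pos, as_, aa_) {
      out <- numeric(length(src_pos))
      k <- length(as_)
      lo <- src_pos < as_[1L]
      hi <- src_pos > as_[k]
      if (any(lo) && as_[2L] > as_[1L]) {
        slope <- (aa_[2L] - aa_[1L]) / (as_[2L] - as_[1L])
        out[lo] <- slope * (src_pos[lo] - as_[1L])
      }
      if (any(hi) && as_[k] > as_[k - 1L]) {
        slope <- (aa_[k] - aa_[k - 1L]) / (as_[k] - as_[k - 1L])
        out[hi] <- slope * (src_pos[hi] - as_[k])
      }
      out
    }

    rows <- data.frame(lg = lg, marker_id = shared,
                       radtag_id = mm$radtag_id[match(shared, mm$marker_id)],
                       pos_cM = avg)
    only_m <- setdiff(mm$marker_id, shared)
    if (length(only_m)) {
      sp <- mm$pos_cM[match(only_m, mm$marker_id)]
      rows <- rbind(rows, data.frame(
        lg = lg, marker_id = only_m,
        radtag_id = mm$radtag_id[match(only_m, mm$marker_id)],
        pos_cM = interp(sp, mpos, avg)))
    }
    only_f <- setdiff(fm$marker_id, shared)
    if (length(only_f)) {
      sp <- fm$pos_cM[match(only_f, fm$marker_id)]
      rows <- rbind(rows, data.frame(
        lg = lg, marker_id = only_f,
        radtag_id = fm$radtag_id[match(only_f, fm$marker_id)],
        pos_cM = interp(sp, fpos, avg)))
    }
    rows$pos_cM <- pmax(rows$pos_cM, 0)
    pieces[[lg]] <- rows
  }
  linkage_map(do.call(rbind, lapply(pieces, as.data.frame)), "averaged")
}

#' Summary metrics for one or more linkage maps
#'
#' Computes, per linkage group and per map: number of SNPs, number of unique
#' positions, length (maximum position), and the non-zero interval (mean
#' positive gap between consecutive unique positions). When both a male and
#' a female map are supplied the per-LG F:M length ratio is added. The
#' `Total` row sums SNPs, unique positions and lengths and reports the
#' total-length F:M ratio; the `MapAvg` row reports unweighted per-LG means
#' (including the mean of per-LG F:M ratios — both ratio summaries are
#' emitted because a map-level ratio can be read either way).
#'
#' @param averaged,male,female `linkage_map`s (any subset, at least one).
#' @return data.frame with one row per LG plus `MapAvg` and `Total` rows,
#'   columns suffixed by map label.
#' @export
summarize_map <- function(averaged = NULL, male = NULL, female = NULL) {
  maps <- Filter(Negate(is.null),
                 list(avg = averaged, male = male, female = female))
  if (!length(maps)) stop("supply at least one map")
  lgs <- unique(unlist(lapply(maps, function(m) unique(m$lg))))
  lgs <- lgs[order(suppressWarnings(as.numeric(gsub("\\D", "", lgs))), lgs)]

  per_lg <- function(map, lg) {
    pos <- map$pos_cM[map$lg == lg]
    upos <- sort(unique(pos))
    gaps <- diff(upos)
    data.frame(n_snps = length(pos), n_unique = length(upos),
               length_cM = if (length(pos)) max(pos) else NA_real_,
               nonzero_interval_cM = if (length(gaps)) mean(gaps[gaps > 0])
               else NA_real_)
  }
  out <- data.frame(lg = c(lgs, "MapAvg", "Total"))
  for (lab in names(maps)) {
    rows <- do.call(rbind, lapply(lgs, per_lg, map = maps[[lab]]))
    tot <- data.frame(n_snps = sum(rows$n_snps), n_unique = sum(rows$n_unique),
                      length_cM = sum(rows$length_cM),
                      nonzero_interval_cM = NA_real_)
    avg <- data.frame(n_snps = mean(rows$n_snps), n_unique = mean(rows$n_unique),
                      length_cM = mean(rows$length_cM),
                      nonzero_interval_cM = mean(rows$nonzero_interval_cM,
                                                 na.rm = TRUE))
    all_rows <- rbind(rows, avg, tot)
    names(all_rows) <- paste0(names(all_rows), "_", lab)
    out <- cbind(out, all_rows)
  }
  if (all(c("male", "female") %in% names(maps))) {
    ratio <- out$length_cM_female / out$length_cM_male
    n_lg <- length(lgs)
    ratio[n_lg + 1L] <- mean(ratio[seq_len(n_lg)])  # MapAvg: mean of per-LG ratios
    # Total: ratio of total lengths (already implied by the division above)
    out$fm_ratio <- ratio
  }
  rownames(out) <- NULL
  out
}

#' Expected genome coverage of a linkage map
#'
#' `c = 1 - exp(-2 d n / L)`, the probability that a random genome location
#' lies within `d` cM of some marker, where `d` is the average marker
#' spacing, `n` the number of markers and `L` the map length.
#'
#' @param d average marker spacing (cM).
#' @param n number of markers.
#' @param L map length (cM), must be positive.
#' @return coverage in `[0, 1)`.
#' @export
genome_coverage <- function(d, n, L) {
  stopifnot(d >= 0, n >= 0)
  if (any(L <= 0)) stop("map length L must be positive")
  1 - exp(-2 * d * n / L)
}

#' Locate markers on a linkage map
#'
#' Resolves each queried marker id to its LG and position, flags ids absent
#' from the map, and summarises per-LG hit counts with the min-max cM span
#' of the hits — the usual way of asking where a set of sex-linked markers
#' concentrates.
#'
#' @param map a [linkage_map].
#' @param marker_ids character vector of ids to place.
#' @return list with `table` (`marker_id`, `lg`, `pos_cM`, `placed`) and
#'   `summary` (`lg`, `n_hits`, `span_min_cM`, `span_max_cM`).
#' @export
locate_markers <- function(map, marker_ids) {
  idx <- match(marker_ids, map$marker_id)
  tab <- data.frame(
    marker_id = marker_ids,
    lg = ifelse(is.na(idx), NA_character_, map$lg[idx]),
    pos_cM = ifelse(is.na(idx), NA_real_, map$pos_cM[idx]),
    placed = !is.na(idx)
  )
  placed <- tab[tab$placed, , drop = FALSE]
  summary <- if (nrow(placed)) {
    do.call(rbind, lapply(split(placed, placed$lg), function(s) {
      data.frame(lg = s$lg[1L], n_hits = nrow(s),
                 span_min_cM = min(s$pos_cM), span_max_cM = max(s$pos_cM))
    }))
  } else {
    data.frame(lg = character(), n_hits = integer(),
               span_min_cM = numeric(), span_max_cM = numeric())
  }
  rownames(summary) <- NULL
  list(table = tab, summary = summary)
}
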