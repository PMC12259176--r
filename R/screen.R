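## Unit/session inclusion filters and pseudopopulation assembly.

# mean firing rate (spikes/s) per unit x trial in a window
session_window_rates <- function(session, window) {
  check_window(window, session$bin_edges)
  wb <- window_bins(window, session$bin_edges)
  cnt <- session$counts[, , wb$idx, drop = FALSE]
  # partial bins: scale expected contribution by overlap fraction
  frac <- wb$overlap_ms / diff(session$bin_edges)[wb$idx]
  sc <- sweep(cnt, 3, frac, `*`)
  apply(sc, c(1, 2), sum) / (wb$duration_ms / 1000)
}

#' Unit responsiveness filter
#'
#' Includes a unit when its post-stimulus firing differs from its
#' pre-stimulus firing across all trials (paired two-sided t-test at
#' `alpha`). Zero-variance differences make the t-test degenerate: a unit
#' whose post counts equal its pre counts on every trial gets `p = 1`
#' (excluded), while a perfectly constant nonzero response gets `p = 0`
#' (included).
#'
#' @param session A `session_recording`.
#' @param post_window,pre_window Spike-count windows in ms.
#' @param alpha Inclusion threshold on the p-value.
#' @return A tibble (`unit_id`, `p_value`, `include`) with attribute
#'   `n_excluded`.
#' @export
responsiveness_filter <- function(session, post_window = c(50, 350),
                                  pre_window = c(-300, 0), alpha = 0.10) {
  post <- session_window_rates(session, post_window)
  pre <- session_window_rates(session, pre_window)
  p <- vapply(seq_len(nrow(post)), function(u) {
    d <- post[u, ] - pre[u, ]
    if (length(d) < 2 || sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
    t.test(post[u, ], pre[u, ], paired = TRUE)$p.value
  }, numeric(1))
  out <- tibble::tibble(
    unit_id = session$units$unit_id,
    p_value = p,
    include = p < alpha
  )
  attr(out, "n_excluded") <- sum(!out$include)
  out
}

#' Session stability filter
#'
#' A session fails when (a) its overall baseline firing rate in the first
#' fifth versus the last fifth of trials differs by more than `fold_limit`,
#' or (b) baseline rates preceding novel versus repeated images differ
#' (two-sided t-test, `p < baseline_alpha`).
#'
#' @param session A `session_recording`.
#' @param baseline_window Window in ms used as baseline (default 500 ms
#'   before onset).
#' @param fold_limit Maximum allowed first/last-fifth baseline ratio.
#' @param baseline_alpha Alpha for the novel-vs-repeated baseline t-test.
#' @return A one-row tibble with the fold ratio, the t-test p, and
#'   `stable`.
#' @export
stability_filter <- function(session, baseline_window = c(-500, 0),
                             fold_limit = 2, baseline_alpha = 0.01) {
  n_trials <- nrow(session$trials)
  if (min(table(session$trials$novelty)) < 2) {
    abort("need at least two trials of each novelty for the stability filter.")
  }
  base <- colMeans(session_window_rates(session, baseline_window))  # per trial
  fifth <- max(2L, floor(n_trials / 5))
  first <- mean(base[seq_len(fifth)])
  last <- mean(base[seq.int(n_trials - fifth + 1L, n_trials)])
  ratio <- max(first, last) / max(min(first, last), 1e-12)
  is_nov <- session$trials$novelty == "novel"
  p_nr <- if (sd(base[is_nov]) == 0 && sd(base[!is_nov]) == 0) 1 else
    t.test(base[is_nov], base[!is_nov])$p.value
  tibble::tibble(
    fold_ratio = ratio,
    fold_ok = ratio <= fold_limit,
    baseline_novrep_p = p_nr,
    baseline_ok = p_nr >= baseline_alpha,
    stable = ratio <= fold_limit & p_nr >= baseline_alpha
  )
}

#' Subset a session to the units passed by a screen report
#'
#' Filters never modify counts; this helper materializes the unit mask.
#'
#' @param session A `session_recording`.
#' @param report Tibble from [responsiveness_filter()] (or any tibble with
#'   `unit_id` and `include`).
#' @return The session restricted to included units.
#' @export
apply_screen <- function(session, report) {
  keep <- which(session$units$unit_id %in% report$unit_id[report$include])
  session$counts <- session$counts[keep, , , drop = FALSE]
  session$units <- session$units[keep, , drop = FALSE]
  session
}

# ---------------------------------------------------------------------------
# pseudopopulation
# ---------------------------------------------------------------------------

# complete novel/repeat image pairs of a session, with alignment metadata
session_pairs <- function(session, mb_bins, nback_strata, on_target_only) {
  tr <- session$trials
  nov <- tr[tr$novelty == "novel", c("trial_index", "image_id")]
  rep_ <- tr[tr$novelty == "repeated", c("trial_index", "image_id", "n_back", "on_target")]
  pairs <- dplyr::inner_join(nov, rep_, by = "image_id",
                             suffix = c("_novel", "_repeated"))
  if (on_target_only) pairs <- pairs[!is.na(pairs$on_target) & pairs$on_target, ]
  mem <- setNames(session$images$memorability, session$images$image_id)
  pairs$memorability <- unname(mem[pairs$image_id])
  pairs$mb_bin <- pmin(mb_bins, 1L + floor(pairs$memorability * mb_bins))
  pairs$nback_stratum <- if (identical(nback_strata, "pooled")) "all" else
    as.character(pairs$n_back)
  pairs$stratum <- paste(pairs$mb_bin, pairs$nback_stratum, sep = "/")
  pairs
}

#' Assemble a pseudopopulation from screened sessions
#'
#' Units recorded in separate sessions are concatenated as if simultaneous.
#' Complete novel/repeat image pairs are grouped into strata defined by a
#' memorability bin and an n-back stratum; within each stratum the number of
#' pseudoimages equals the minimum eligible pair count across sessions, and
#' excess pairs in longer sessions are dropped uniformly at random (seeded).
#' Every (unit, pseudoimage) cell holds the unit's counts for one real
#' image's novel and repeated trials, and all real images contributing to a
#' pseudoimage share a memorability bin and n-back stratum.
#'
#' @param sessions A `session_recording` or list of them.
#' @param mb_bins Number of equal-width memorability bins on `[0, 1]` used
#'   to define "similar memorability".
#' @param nback_strata `"level"` (each n-back gap its own stratum) or
#'   `"pooled"`.
#' @param on_target_only Use only on-target repeats (default `TRUE`).
#' @param seed Optional integer seed for the dropped-trial selection.
#' @param strict Error (rather than warn and drop) when a stratum present in
#'   one session is empty in another.
#' @return A `pseudopop` object: `counts` is a units x pseudoimages x
#'   condition (novel, repeated) x bins integer array; `pseudoimages` is a
#'   tibble with `pseudoimage`, `mb_bin`, `memorability` (mean of the
#'   contributing images), `n_back` stratum label, and the contributing
#'   image ids per session.
#' @export
assemble_pseudopopulation <- function(sessions, mb_bins = 10,
                                      nback_strata = c("level", "pooled"),
                                      on_target_only = TRUE, seed = NULL,
                                      strict = FALSE) {
  if (inherits(sessions, "session_recording")) sessions <- list(sessions)
  nback_strata <- match.arg(nback_strata)
  pair_sets <- lapply(sessions, session_pairs, mb_bins = mb_bins,
                      nback_strata = nback_strata, on_target_only = on_target_only)
  strata <- sort(unique(unlist(lapply(pair_sets, function(p) p$stratum))))
  counts_per <- vapply(pair_sets, function(p) {
    vapply(strata, function(s) sum(p$stratum == s), integer(1))
  }, integer(length(strata)))
  counts_per <- matrix(counts_per, nrow = length(strata))
  n_keep <- apply(counts_per, 1, min)
  if (any(n_keep == 0)) {
    msg <- sprintf("%d strata empty in at least one session were dropped.",
                   sum(n_keep == 0))
    if (strict) abort(msg) else if (length(sessions) > 1) warn(msg)
    strata <- strata[n_keep > 0]
    n_keep <- n_keep[n_keep > 0]
  }
  if (length(strata) == 0) abort("no stratum is populated in every session.")

  with_stream(seed, "assemble", {
    # per session: ordered list of retained pairs, aligned by stratum slot
    aligned <- lapply(pair_sets, function(p) {
      kept <- lapply(seq_along(strata), function(si) {
        rows <- p[p$stratum == strata[si], , drop = FALSE]
        rows <- rows[sample.int(nrow(rows)), , drop = FALSE]  # unbiased drop
        rows[seq_len(n_keep[si]), , drop = FALSE]
      })
      dplyr::bind_rows(kept)
    })
    n_pseudo <- sum(n_keep)
    n_bins <- dim(sessions[[1]]$counts)[3]
    bin_edges <- sessions[[1]]$bin_edges
    for (s in sessions) {
      if (!isTRUE(all.equal(s$bin_edges, bin_edges))) {
        abort("all sessions must share bin edges.")
      }
    }
    unit_ids <- unlist(lapply(seq_along(sessions), function(k) {
      paste0("s", k, "_", sessions[[k]]$units$unit_id)
    }))
    counts <- array(0L, dim = c(length(unit_ids), n_pseudo, 2L, n_bins))
    row0 <- 0L
    for (k in seq_along(sessions)) {
      ses <- sessions[[k]]
      al <- aligned[[k]]
      nu <- dim(ses$counts)[1]
      counts[row0 + seq_len(nu), , 1L, ] <- ses$counts[, al$trial_index_novel, , drop = FALSE]
      counts[row0 + seq_len(nu), , 2L, ] <- ses$counts[, al$trial_index_repeated, , drop = FALSE]
      row0 <- row0 + nu
    }
    mem_mat <- vapply(aligned, function(a) a$memorability, numeric(n_pseudo))
    mem_mat <- matrix(mem_mat, nrow = n_pseudo)
    pseudo <- tibble::tibble(
      pseudoimage = seq_len(n_pseudo),
      stratum = aligned[[1]]$stratum,
      mb_bin = aligned[[1]]$mb_bin,
      n_back = aligned[[1]]$nback_stratum,
      memorability = rowMeans(mem_mat),
      images = lapply(seq_len(n_pseudo), function(i) {
        vapply(aligned, function(a) a$image_id[i], character(1))
      })
    )
    structure(
      list(counts = counts, pseudoimages = pseudo, unit_ids = unit_ids,
           bin_edges = bin_edges),
      class = "pseudopop"
    )
  })
}

#' @export
print.pseudopop <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<pseudopop: %d units x %d pseudoimages x {novel, repeated} x %d bins>\n",
              d[1], d[2], d[4]))
  invisible(x)
}

#' Break the memorability alignment of a pseudopopulation
#'
#' Within each unit independently, permutes which image pair feeds which
#' pseudoimage slot, preserving each image's own novel/repeated pairing.
#' This destroys the across-unit alignment of pseudoimages by memorability
#' while leaving every unit's marginal novel and repeated count
#' distributions exactly unchanged.
#'
#' @param pop A `pseudopop`.
#' @param seed Optional integer seed.
#' @return A `pseudopop` with shuffled unit-wise alignment.
#' @export
shuffle_alignment <- function(pop, seed = NULL) {
  n_units <- dim(pop$counts)[1]
  n_pseudo <- dim(pop$counts)[2]
  with_stream(seed, "shuffle", {
    for (u in seq_len(n_units)) {
      perm <- sample.int(n_pseudo)
      pop$counts[u, , , ] <- pop$counts[u, perm, , , drop = FALSE]
    }
  })
  pop
}

#' Spike counts of a pseudopopulation in a window
#'
#' @param pop A `pseudopop`.
#' @param window `[start, end]` ms window.
#' @return List with matrices `novel` and `repeated` (units x pseudoimages)
#'   of window spike counts, plus `duration_s`.
#' @export
window_counts <- function(pop, window) {
  check_window(window, pop$bin_edges)
  wb <- window_bins(window, pop$bin_edges)
  frac <- wb$overlap_ms / diff(pop$bin_edges)[wb$idx]
  pick <- function(cond) {
    cnt <- pop$counts[, , cond, wb$idx, drop = FALSE]
    dim(cnt) <- dim(cnt)[c(1, 2, 4)]
    sc <- sweep(cnt, 3, frac, `*`)
    apply(sc, c(1, 2), sum)
  }
  list(novel = pick(1L), repeated = pick(2L),
       duration_s = wb$duration_ms / 1000)
}

#' Subset a pseudopopulation to selected pseudoimages
#' @param pop A `pseudopop`.
#' @param idx Integer indices of pseudoimages to keep.
#' @return A `pseudopop` restricted to those pseudoimages.
#' @export
subset_pseudoimages <- function(pop, idx) {
  pop$counts <- pop$counts[, idx, , , drop = FALSE]
  pop$pseudoimages <- pop$pseudoimages[idx, , drop = FALSE]
  pop$pseudoimages$pseudoimage <- seq_len(nrow(pop$pseudoimages))
  pop
}
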