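# Shared fixture builders. Everything is generated in code at test time.

# Narrow-window configs keep simulations fast where the pre-stimulus epoch
# is not needed.
fast_cfg <- function(cfg = itc_config(), window = c(0, 520)) {
  cfg$trial_window <- window
  cfg
}

# Simulate a single-session pseudopopulation.
make_pop <- function(n_img = 60, n_units = 40, cfg = fast_cfg(), seed = 1,
                     levels = c(1, 2, 4), core = NULL) {
  core <- core %||% floor(n_img / (length(levels) - 0.5) / 1.05)
  imgs <- gen_images(n_img, seed = seed)
  seqn <- gen_sequence(imgs, nback_spec(levels, core_count = core), seed = seed)
  units <- gen_units(cfg, n_units, imgs, seed = seed)
  ses <- suppressWarnings(simulate_session(units, seqn, imgs, cfg, seed = seed))
  list(images = imgs, sequence = seqn, units = units, session = ses,
       pop = assemble_pseudopopulation(ses, seed = seed))
}

# Hand-built session_recording with explicit counts (units x trials x bins).
make_session <- function(counts, bin_edges, novelty = NULL, images = NULL) {
  d <- dim(counts)
  novelty <- novelty %||% rep(c("novel", "repeated"), length.out = d[2])
  image_id <- sprintf("img%03d", rep(seq_len(ceiling(d[2] / 2)), each = 2)[seq_len(d[2])])
  trials <- tibble::tibble(
    trial_index = seq_len(d[2]),
    image_id = image_id,
    novelty = novelty,
    n_back = ifelse(novelty == "repeated", 1L, NA_integer_),
    on_target = ifelse(novelty == "repeated", TRUE, NA)
  )
  images <- images %||% tibble::tibble(
    image_id = unique(image_id),
    memorability = seq(0.05, 0.95, length.out = length(unique(image_id)))
  )
  structure(
    list(counts = counts, trials = trials, images = images,
         units = tibble::tibble(unit_id = sprintf("u%02d", seq_len(d[1]))),
         bin_edges = bin_edges, config_name = "hand-built"),
    class = "session_recording"
  )
}

# Hand-built single-bin pseudopopulation from novel/repeated count matrices.
make_counts_pop <- function(novel, repeated, memorability,
                            bin_edges = c(0, 200)) {
  n_units <- nrow(novel); n_img <- ncol(novel)
  counts <- array(0L, dim = c(n_units, n_img, 2L, length(bin_edges) - 1L))
  counts[, , 1L, 1L] <- novel
  counts[, , 2L, 1L] <- repeated
  structure(
    list(counts = counts,
         pseudoimages = tibble::tibble(pseudoimage = seq_len(n_img),
                                       memorability = memorability,
                                       mb_bin = NA_integer_,
                                       n_back = NA_character_),
         unit_ids = sprintf("u%02d", seq_len(n_units)),
         bin_edges = bin_edges),
    class = "pseudopop"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
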