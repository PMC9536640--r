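# Shared fixtures, built in code at test time.

# brute-force parameter oracle: enumerate every trainable array and multiply
# its dimensions (independent of count_parameters' length()-based walk)
oracle_param_count <- function(block) {
  refs <- nn_parameters(block)
  s <- 0
  for (r in refs) {
    w <- r$env[[r$field]]
    s <- s + if (is.null(dim(w))) length(w) else prod(dim(w))
  }
  s
}

# a tiny assembled model that exercises every block type
tiny_config <- function(classes = 5) {
  model_config(num_classes = classes, stage_widths = c(4, 4, 8),
               ghost_counts = c(1, 1, 1), expansion = 4,
               cbam_reduction = 4, input_side = 32)
}

# manifest with k classes of the given sizes
fake_manifest <- function(sizes) {
  do.call(rbind, lapply(seq_along(sizes), function(k) {
    data.frame(path = sprintf("c%02d/i%03d.png", k, seq_len(sizes[k])),
               identity = sprintf("c%02d", k), stringsAsFactors = FALSE)
  }))
}

# one shared small herd on disk per test session
herd_dir <- local({
  dir <- NULL
  function(per_id = 6, seed = 11, side = 64) {
    key <- file.path(tempdir(),
                     sprintf("herd_%d_%d_%d", per_id, seed, side))
    if (!dir.exists(key)) {
      spec <- herd_spec(images_per_identity = per_id, master_seed = seed,
                        side = side)
      generate_dataset(spec, key)
    }
    key
  }
})

# tiny content hash (no external digest dependency): file size + checksum
digest_file <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  paste0(length(b), "-", sum(as.integer(b) * (seq_along(b) %% 97)) %% 1e9)
}
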