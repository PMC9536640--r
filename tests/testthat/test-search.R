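test_that("enumeration counts members and honors the structural rules", {
  single <- search_space(width_choices = 32, ghost_choices = 1,
                         expansions = 4, exit_options = TRUE)
  expect_length(enumerate_configs(single), 1)
  two_widths <- search_space(width_choices = list(c(16, 32), 32, 32),
                             ghost_choices = 1)
  expect_length(enumerate_configs(two_widths), 2)
  sp <- search_space(width_choices = c(16, 32),
                     ghost_choices = list(0:1, 0:1, 0:1))
  for (cfg in enumerate_configs(sp)) {
    expect_true(all(diff(cfg$options$ghost_counts) >= 0))
    expect_true(all(diff(cfg$options$stage_widths) >= 0))
  }
  expect_error(enumerate_configs(
    search_space(width_choices = list(c(64), c(32), c(16)),
                 ghost_choices = 0)), "empty")
})

test_that("closed-form search scores equal built-model counts on sampled members", {
  sp <- search_space(width_choices = c(8, 16, 24),
                     ghost_choices = list(0:1, 0:1, 1:2),
                     exit_options = c(TRUE, FALSE),
                     use_cbam = TRUE, cbam_reductions = 4)
  members <- enumerate_configs(sp)
  set.seed(99)
  for (cfg in members[sample(length(members), 20)])
    expect_equal(config_param_count(cfg),
                 count_parameters(assemble_model(cfg)))
})

test_that("target search is deterministic and equals the exhaustive brute-force minimum", {
  sp <- search_space(width_choices = c(8, 16, 24, 32),
                     ghost_choices = list(0:1, 0:1, 0:1),
                     exit_options = c(TRUE, FALSE))
  members <- enumerate_configs(sp)
  expect_lte(length(members), 200)
  target <- 500000
  res1 <- search_to_target(sp, target)
  res2 <- search_to_target(sp, target)
  expect_equal(res1$best$options, res2$best$options)
  expect_equal(res1$gap, res2$gap)
  expect_equal(res1$n_evaluated, length(members))
  # brute force through actually-built models
  gaps <- vapply(members, function(cfg)
    abs(count_parameters(assemble_model(cfg)) - target), numeric(1))
  expect_equal(res1$gap, min(gaps))
  expect_equal(res1$best$options, members[[which.min(gaps)]]$options)
})

test_that("a singleton space containing the target architecture reaches gap zero", {
  sp <- search_space(width_choices = 32, ghost_choices = 2)
  own <- config_param_count(enumerate_configs(sp)[[1]])
  expect_equal(search_to_target(sp, own)$gap, 0)
})

test_that("ledger search pins the baseline exactly and publishes non-negative gaps", {
  tab <- ledger_search(width_choices = c(16, 24, 32, 40, 48, 56, 64),
                       ghost_choices = list(0:2, 0:3, 0:4),
                       expansions = c(2, 4),
                       exit_options = c(TRUE, FALSE))
  expect_identical(tab$variant,
                   c("ResNet50", "A", "B", "C", "Ours"))
  expect_equal(tab$gap[tab$variant == "ResNet50"], 0)
  expect_true(all(tab$gap >= 0))
  expect_true(all(tab$gap == floor(tab$gap)))
  cfgs <- attr(tab, "configs")
  # adding the three attention blocks is closed-form additive
  ours <- cfgs$Ours
  no_att <- do.call(model_config,
                    c(list(num_classes = 13),
                      modifyList(ours$options, list(use_cbam = FALSE))[
                        intersect(names(ours$options),
                                  names(formals(model_config)))]))
  cb_sum <- sum(vapply(ours$stages,
                       function(st) params_cbam(st$attention), numeric(1)))
  expect_equal(config_param_count(ours),
               config_param_count(no_att) + cb_sum)
})
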