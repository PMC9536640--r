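test_that("parameter counting agrees with the brute-force enumeration oracle across block types and widths", {
  for (w in c(16, 32, 64, 128, 256)) {
    blocks <- list(
      build_stem(conv_spec(3, 3, w, stride = 2, dilation = 3)),
      build_bottleneck(bottleneck_spec(w, w, 4 * w)),
      build_bottleneck(bottleneck_spec(4 * w, w, 4 * w)),
      build_ghost_module(ghost_module_spec(w, w)),
      build_ghost_bottleneck(ghost_bottleneck_spec(w, w, w)),
      build_cbam(cbam_spec(w, 16, 7)))
    for (b in blocks)
      expect_equal(count_parameters(b), oracle_param_count(b))
  }
  expect_equal(count_parameters(ghostherd:::nn_relu()), 0)
})

test_that("closed-form block counts equal the counts of built blocks", {
  for (w in c(16, 48, 96)) {
    sp <- bottleneck_spec(w, w, 4 * w, stride = 2)
    expect_equal(params_bottleneck(sp), count_parameters(build_bottleneck(sp)))
    gm <- ghost_module_spec(w, 2 * w, ratio_s = 2, cheap_kernel_d = 3)
    expect_equal(params_ghost_module(gm),
                 count_parameters(build_ghost_module(gm)))
    gb <- ghost_bottleneck_spec(w, 2 * w, 2 * w, stride = 2)
    expect_equal(params_ghost_bottleneck(gb),
                 count_parameters(build_ghost_bottleneck(gb)))
    cb <- cbam_spec(4 * w, 16, 7)
    expect_equal(params_cbam(cb), count_parameters(build_cbam(cb)))
  }
})

test_that("the reference baseline reproduces the published counts", {
  m13 <- build_reference_resnet50(13)
  expect_equal(count_parameters(m13), 23534669)
  expect_equal(resnet50_param_count(13), 23534669)
  expect_equal(resnet50_param_count(1000), 25557032)
  # head sizes differ by exactly (2048 + 1) per class
  expect_equal(resnet50_param_count(1000) - resnet50_param_count(13),
               (2048 + 1) * (1000 - 13))
})

test_that("FP32 sizes follow the 4-byte MiB convention with half-up rounding", {
  expect_equal(fp32_size_mib(947226), 3.61)
  expect_equal(fp32_size_mib(23534669), 89.78)
  expect_equal(fp32_size_mib(923125), 3.52)
  expect_equal(fp32_size_mib(1694925), 6.47)
  expect_equal(fp32_size_mib(1687437), 6.44)
  expect_equal(fp32_size_mib(0), 0)
  expect_error(fp32_size_mib(-1), "non-negative")
  # monotone non-decreasing in the count
  cnts <- sort(sample.int(3e7, 50))
  expect_true(all(diff(fp32_size_mib(cnts)) >= 0))
})

test_that("MAC counting matches closed forms, is additive, and ignores dilation", {
  conv <- build_stem(conv_spec(3, 3, 64, stride = 1, dilation = 1))
  expect_equal(count_macs(conv, c(224, 224, 3)), 9 * 3 * 64 * 224 * 224)
  expect_equal(count_macs(conv, c(224, 224, 3)), 86704128)
  fc <- ghostherd:::nn_linear(2048, 13)
  expect_equal(count_macs(ghostherd:::nn_sequential(gap = ghostherd:::nn_global_avgpool(), fc = fc),
                          c(7, 7, 2048)), 2048 * 13)
  # additive over sequential composition
  s1 <- build_stem(conv_spec(3, 3, 8))
  s2 <- build_bottleneck(bottleneck_spec(8, 8, 32))
  seqm <- ghostherd:::nn_sequential(a = build_stem(conv_spec(3, 3, 8)),
                        b = build_bottleneck(bottleneck_spec(8, 8, 32)))
  expect_equal(count_macs(seqm, c(16, 16, 3)),
               count_macs(s1, c(16, 16, 3)) + count_macs(s2, c(16, 16, 8)))
  # dilation adds no operations
  d3 <- build_stem(conv_spec(3, 3, 16, dilation = 3))
  d1 <- build_stem(conv_spec(3, 3, 16, dilation = 1))
  expect_equal(count_macs(d3, c(32, 32, 3)), count_macs(d1, c(32, 32, 3)))
})

test_that("compression ratio reproduces the printed reduction factor", {
  expect_equal(compression_ratio(23534669, 947226), 24.85)
  expect_equal(compression_ratio(5, 5), 1)
  expect_equal(compression_ratio(100, 4), 25)
  expect_error(compression_ratio(10, 0), "positive")
})

test_that("ablation report conserves totals and registers printed gaps", {
  cfg <- tiny_config()
  rep <- accounting_report(assemble_model(cfg), c(32, 32, 3))
  expect_equal(rep$totals$params, sum(rep$rows$params))
  expect_equal(rep$totals$macs, sum(rep$rows$macs))
  expect_equal(rep$totals$params, config_param_count(cfg))

  f <- tempfile(fileext = ".csv")
  tab <- ablation_report(list(tinyA = cfg, tinyB = cfg),
                         input_shape = c(32, 32, 3),
                         printed = c(tinyA = 1000), file = f)
  expect_identical(tab$params[1], tab$params[2])   # same model, same row
  expect_equal(tab$gap[1], abs(tab$params[1] - 1000))
  expect_true(is.na(tab$gap[2]))
  expect_identical(names(utils::read.csv(f)),
                   c("variant", "params", "size_mib", "macs",
                     "printed_params", "gap"))
})
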