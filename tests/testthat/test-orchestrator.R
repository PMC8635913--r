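test_that("round bookkeeping: one record per round, deterministic reruns", {
  fit <- fedchain(quick_cfg(T_max = 1))
  expect_identical(nrow(fit$records), 1L)
  a <- fedchain(quick_cfg(T_max = 3, sigma = 4, poisoned_fraction = 0.2))
  b <- fedchain(quick_cfg(T_max = 3, sigma = 4, poisoned_fraction = 0.2))
  expect_identical(a$records, b$records)
  expect_identical(a$params$values, b$params$values)
})

test_that("a zero privacy budget stops training after the first release", {
  fit <- fedchain(quick_cfg(T_max = 10, sigma = 4, epsilon = 0,
                            check_budget = TRUE))
  expect_identical(nrow(fit$records), 1L)
  expect_identical(fit$stop_reason, "budget_exhausted")
})

test_that("spent epsilon never decreases over a long noised run", {
  fit <- cached("dp_run", fedchain(quick_cfg(T_max = 15, sigma = 4)))
  expect_false(is.unsorted(fit$records$spent_epsilon))
  expect_gt(fit$records$spent_epsilon[15], 0)
})

test_that("with no noise, attack or verification the pipeline IS FedAvg", {
  cfg <- quick_cfg(n = 300, T_max = 10, verification = FALSE, seed = 5)
  fit <- fedchain(cfg)
  ds <- sim_pima(cfg$n, cfg$seed, cfg$positive_rate, cfg$noise_scale)
  sp <- train_test_split(ds, cfg$test_fraction, cfg$seed)
  pt <- partition_devices(sp$train, cfg$K, cfg$seed)
  ref <- fedavg_reference(
    init_params(cfg$arch_id, cfg$seed), pt$shards, rounds = 10,
    batch_size = cfg$batch_size, iterations = cfg$local_iterations,
    lr = cfg$lr, seed = cfg$seed, prep = feature_prep(sp$train),
    clipper = clipper_state(gamma = cfg$gamma, beta = cfg$beta,
                            fixed_C = cfg$C, prior_threshold = cfg$G,
                            sigma = 0))
  expect_identical(fit$params$values, ref$params$values)  # bit-identical
})

test_that("every run leaves an auditable chain consistent with its records", {
  fit <- cached("defended_run",
                fedchain(quick_cfg(n = 768, K = 20, M = 5, n_miners = 10,
                                   T_max = 12, poisoned_fraction = 0.3,
                                   krum_f = 6, seed = 1)))
  expect_invisible(audit_chain(fit$chain, fit$keys))
  expect_length(fit$chain, nrow(fit$records) + 1L)      # genesis + rounds
  for (i in seq_len(nrow(fit$records))) {
    blk <- fit$chain[[i + 1L]]
    expect_identical(length(blk$transactions), fit$records$n_qualified[i])
    expect_identical(blk$round, fit$records$round[i])
  }
  # persisted chain reloads, audits, and detects single-bit tampering
  dir <- withr::local_tempdir()
  write_chain(fit$chain, dir)
  expect_true(audit_chain(read_chain(dir), fit$keys))
  target <- file.path(dir, "blk_00005.bin")
  bytes <- readBin(target, "raw", n = file.size(target))
  bytes[200] <- xor(bytes[200], as.raw(1))
  writeBin(bytes, target)
  tampered <- tryCatch(audit_chain(read_chain(dir), fit$keys),
                       error = function(e) conditionMessage(e))
  expect_match(tampered, "audit|truncated|magic")
})

test_that("blacklisted devices stop submitting transactions", {
  fit <- cached("defended_run",
                fedchain(quick_cfg(n = 768, K = 20, M = 5, n_miners = 10,
                                   T_max = 12, poisoned_fraction = 0.3,
                                   krum_f = 6, seed = 1)))
  r <- fit$records
  expect_gt(r$blacklist_size[nrow(r)], 0)               # cascade happened
  # submitters at round t = K minus the blacklist after round t-1
  expect_equal(r$n_active,
               fit$config$K - c(0L, head(r$blacklist_size, -1L)))
})

test_that("malicious verifiers lose reputation; honest ones gain it", {
  fit <- fedchain(quick_cfg(n = 400, K = 10, M = 3, n_miners = 6,
                            T_max = 6, n_malicious_verifiers = 1,
                            seed = 8))
  rep <- fit$reputation$reputation
  served <- unlist(strsplit(fit$records$committee, ";"))
  mal <- "m1"
  honest_served <- setdiff(intersect(served, paste0("m", 1:6)), mal)
  expect_true(all(rep[honest_served] >= 10))
  if (mal %in% served) expect_lt(rep[mal], 10)
})

test_that("the fitted object exposes the standard modelling interface", {
  fit <- cached("dp_run", fedchain(quick_cfg(T_max = 15, sigma = 4)))
  expect_s3_class(fit, "fedchain")
  expect_output(print(fit), "attack success rate")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.fedchain")
  expect_output(print(sm), "rounds run")
  cf <- coef(fit)
  expect_length(cf, 9L)
  expect_identical(names(cf)[9], "(bias)")
  pr <- predict(fit, type = "prob")
  expect_true(all(pr >= 0 & pr <= 1))
  cl <- predict(fit)
  expect_true(all(cl %in% 0:1))
  expect_length(residuals(fit), nrow(fit$data$test$features))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
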