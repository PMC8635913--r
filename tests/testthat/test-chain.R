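test_that("SHA-256 and HMAC match the reference test vectors", {
  hex <- function(r) paste(format(r), collapse = "")
  expect_identical(hex(sha256_raw(charToRaw("abc"))),
                   paste0("ba7816bf8f01cfea414140de5dae2223",
                          "b00361a396177a9cb410ff61f20015ad"))
  expect_identical(hex(sha256_raw(raw(0))),
                   paste0("e3b0c44298fc1c149afbf4c8996fb924",
                          "27ae41e4649b934ca495991b7852b855"))
  expect_identical(
    hex(hmac_sha256_raw(charToRaw("key"),
                        charToRaw("The quick brown fox jumps over the lazy dog"))),
    paste0("f7bc83f430538424b13298e6aa6fb143",
           "ef4d59a14946175997479dbc2d1a3cd8"))
})

test_that("signatures verify for the signer and fail for everyone else", {
  keys <- party_keys(c("a", "b"), seed = 3)
  msg <- charToRaw("round 7 payload")
  sig <- sign_bytes(keys, "a", msg)
  expect_true(verify_bytes(keys, "a", msg, sig))
  expect_false(verify_bytes(keys, "b", msg, sig))
  expect_false(verify_bytes(keys, "a", c(msg, as.raw(0)), sig))
  expect_false(verify_bytes(keys, "a", msg, rev(sig)))
})

test_that("reputation updates floor at zero and blacklist permanently", {
  tab <- reputation_table(c("d1", "d2", "m1"),
                          c("device", "device", "miner"), initial = 2)
  tab <- update_reputation(tab, list(plus = "d1", minus = "d2"))
  expect_identical(unname(tab$reputation[c("d1", "d2")]), c(3L, 1L))
  tab <- update_reputation(tab, list(minus = "d2"))
  expect_identical(unname(tab$reputation["d2"]), 0L)
  expect_true("d2" %in% tab$blacklist)
  expect_false("d2" %in% fedchain:::active_devices(tab))
  tab <- update_reputation(tab, list(minus = "d2"))   # stays floored
  expect_identical(unname(tab$reputation["d2"]), 0L)
  expect_error(update_reputation(tab, list(plus = "ghost")), "unknown")
})

test_that("committee selection is deterministic and reputation-proportional", {
  tab <- reputation_table(c("m1", "m2"), c("miner", "miner"), initial = 1)
  tab$reputation["m2"] <- 3L
  h <- sha256_raw(charToRaw("genesis"))
  expect_identical(select_committee(h, tab, 1), select_committee(h, tab, 1))
  # single eligible miner is always chosen
  solo <- reputation_table("m9", "miner", initial = 5)
  expect_identical(select_committee(h, solo, 1), "m9")
  # frequencies over 1e4 distinct hashes vs 1/4 : 3/4 arcs
  counts <- c(m1 = 0L, m2 = 0L)
  for (i in 1:10000) {
    sel <- select_committee(sha256_raw(charToRaw(paste0("blk", i))), tab, 1)
    counts[sel] <- counts[sel] + 1L
  }
  expect_gt(chisq.test(counts, p = c(1, 3) / 4)$p.value, 0.01)
  # blacklisted miners own no arc
  tab2 <- update_reputation(tab, list(minus = "m1"))  # 1 -> 0, blacklisted
  picks <- unique(vapply(1:50, function(i)
    select_committee(sha256_raw(charToRaw(paste0("x", i))), tab2, 1), ""))
  expect_identical(picks, "m2")
  expect_error(select_committee(h, tab2, 2), "consensus error")
})

test_that("leader choice is deterministic and near-uniform", {
  com <- paste0("m", 1:5)
  h <- sha256_raw(charToRaw("tip"))
  expect_identical(select_leader(com, h), select_leader(com, h))
  expect_identical(select_leader("m7", h), "m7")
  tally <- table(vapply(1:10000, function(i)
    select_leader(com, sha256_raw(charToRaw(paste0("t", i)))), ""))
  expect_true(all(abs(tally - 2000) <= 5 * sqrt(2000 * 0.8)))
})

test_that("blocks serialize canonically and round-trip", {
  keys <- party_keys(c("d1", "m1", "m2", "m3"), seed = 5)
  g <- c(0.25, -1.5, 3)
  tx <- list(device_id = "d1", gradient = g,
             device_sig = sign_bytes(keys, "d1",
                                     fedchain:::tx_message(1, "d1", g)),
             endorsements = lapply(c("m1", "m2"), function(v)
               list(verifier = v,
                    sig = sign_bytes(keys, v, fedchain:::ser_doubles(g)))))
  blk <- build_block(1, prev_hash = sha256_raw(charToRaw("prev")),
                     accepted = list(tx), committee = c("m1", "m2", "m3"),
                     leader_id = "m2", keys = keys)
  bytes <- fedchain:::serialize_block(blk)
  back <- fedchain:::deserialize_block(bytes)
  expect_identical(back$hash, blk$hash)
  expect_identical(back$transactions[[1]]$gradient, g)
  expect_identical(back$leader_id, "m2")
  # empty accepted list still yields a valid, signed block
  empty <- build_block(2, blk$hash, list(), c("m1", "m2", "m3"), "m1", keys)
  expect_true(empty$is_empty)
  expect_length(empty$transactions, 0L)
  # any single-bit mutation changes the digest
  for (k in c(1L, 57L, length(bytes))) {
    mut <- bytes
    mut[k] <- xor(mut[k], as.raw(1))
    expect_false(identical(sha256_raw(mut), blk$hash))
  }
})

test_that("block approval needs a strict 2/3 supermajority", {
  keys <- party_keys(c("d1", "m1", "m2", "m3", "m4", "m5", "m6"), seed = 6)
  com3 <- c("m1", "m2", "m3")
  blk <- build_block(1, raw(32), list(), com3, "m1", keys)
  expect_true(approve_block(blk, com3, keys)$valid)          # 3 > 2
  two <- approve_block(blk, com3, keys, malicious_verifiers = "m3")
  expect_false(two$valid)                                    # 2 > 2 fails
  expect_true(two$block$is_empty)
  expect_identical(two$block$prev_hash, blk$prev_hash)
  com6 <- paste0("m", 1:6)
  blk6 <- build_block(1, raw(32), list(), com6, "m4", keys)
  expect_true(approve_block(blk6, com6, keys,
                            malicious_verifiers = "m6")$valid)  # 5 > 4
  # a forged leader signature is rejected by every honest verifier
  forged <- blk
  forged$leader_sig <- sign_bytes(keys, "m2",
                                  sha256_raw(charToRaw("something else")))
  expect_false(approve_block(forged, com3, keys)$valid)
})
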