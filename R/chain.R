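# --- canonical byte serialization -------------------------------------
# All chain content is serialized to a documented canonical byte layout
# before hashing or signing: fixed-width 8-byte big-endian unsigned
# integers, IEEE-754 big-endian doubles, and length-prefixed byte/string
# fields.  Any single-bit change to a serialized block changes its
# SHA-256 digest.

ser_u64 <- function(x) {
  stopifnot(x >= 0, x < 2^53)
  out <- raw(8)
  for (i in 8:1) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

de_u64 <- function(bytes) {
  v <- as.integer(bytes)
  Reduce(function(a, b) a * 256 + b, v, accumulate = FALSE)
}

ser_bytes <- function(b) c(ser_u64(length(b)), b)
ser_string <- function(s) ser_bytes(charToRaw(as.character(s)))
ser_doubles <- function(v) {
  c(ser_u64(length(v)), writeBin(as.numeric(v), raw(), size = 8,
                                 endian = "big"))
}

# sequential reader over a raw vector
cursor <- function(bytes) {
  e <- new.env(parent = emptyenv())
  e$bytes <- bytes; e$pos <- 0L
  e
}
take <- function(cur, n) {
  if (cur$pos + n > length(cur$bytes)) stop_param("truncated serialization")
  out <- cur$bytes[cur$pos + seq_len(n)]
  cur$pos <- cur$pos + as.integer(n)
  out
}
rd_u64 <- function(cur) de_u64(take(cur, 8))
rd_bytes <- function(cur) take(cur, rd_u64(cur))
rd_string <- function(cur) rawToChar(rd_bytes(cur))
rd_doubles <- function(cur) {
  n <- rd_u64(cur)
  if (n == 0) return(numeric(0))
  readBin(take(cur, 8 * n), "double", n = n, size = 8, endian = "big")
}

# --- simulated signature scheme ---------------------------------------

#' Party keyring with a deterministic signature scheme
#'
#' Generates one key per party from a master seed.  The default scheme is
#' an HMAC-SHA256 simulation: `sign = HMAC(key, message)` and
#' verification recomputes the tag from the keyring.  It provides the
#' sign/verify contract the protocol needs (any mutation of message or
#' signature is detected) while remaining fast enough for large test
#' matrices; key secrecy and forgery resistance are not modelled, and the
#' scheme field is kept so a public-key scheme can be plugged in.
#'
#' @param ids character vector of party identifiers.
#' @param seed master seed for key generation.
#' @param scheme signature scheme identifier.
#' @return object of class `party_keys`.
#' @export
party_keys <- function(ids, seed, scheme = "hmac-sha256-sim") {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_param("duplicate party ids")
  keys <- lapply(ids, function(id)
    sha256_raw(charToRaw(paste0("key\r", seed, "\r", id))))
  names(keys) <- ids
  structure(list(scheme = scheme, keys = keys), class = "party_keys")
}

#' @describeIn party_keys sign a raw message with `id`'s key (32-byte
#'   signature).
#' @param keys a `party_keys` keyring.
#' @param id signer.
#' @param msg raw message.
#' @export
sign_bytes <- function(keys, id, msg) {
  k <- keys$keys[[as.character(id)]]
  if (is.null(k)) stop_param("unknown party id: ", id)
  hmac_sha256_raw(k, msg)
}

#' @describeIn party_keys verify a signature; returns TRUE/FALSE.
#' @param sig raw signature to check.
#' @export
verify_bytes <- function(keys, id, msg, sig) {
  k <- keys$keys[[as.character(id)]]
  if (is.null(k)) return(FALSE)
  identical(as.raw(sig), hmac_sha256_raw(k, msg))
}

# public identifier for a key (display only; verification uses the ring)
public_key <- function(keys, id) sha256_raw(keys$keys[[as.character(id)]])

# --- reputation --------------------------------------------------------

#' Reputation table with blacklist semantics
#'
#' Every participant (device or miner) starts with an integer reputation.
#' Per round, a device whose update was qualified gains 1 and a rejected
#' device loses 1; a verifier agreeing with the final accepted set gains
#' 1, a disagreeing one loses 1; a miner caught signing a falsified
#' result or fake block loses 1.  Reputation is floored at 0, and a
#' participant reaching 0 enters the blacklist permanently: it no longer
#' submits updates nor owns space on the committee hash ring.
#'
#' @param ids participant identifiers.
#' @param roles `"device"` or `"miner"` per id.
#' @param initial initial reputation (the genesis default is 10).
#' @return object of class `reputation_table`.
#' @export
reputation_table <- function(ids, roles, initial = 10) {
  ids <- as.character(ids)
  stopifnot(length(ids) == length(roles), all(roles %in% c("device", "miner")))
  rep <- rep(as.integer(initial), length(ids))
  names(rep) <- ids
  roles <- stats::setNames(as.character(roles), ids)
  structure(list(reputation = rep, roles = roles, blacklist = character()),
            class = "reputation_table")
}

#' @describeIn reputation_table apply one round's +/-1 events.  `events`
#'   is a list with any of `plus` and `minus`, each a vector of ids.
#' @param table a `reputation_table`.
#' @param events list of id vectors.
#' @export
update_reputation <- function(table, events) {
  stopifnot(inherits(table, "reputation_table"))
  all_ids <- c(events$plus, events$minus)
  unknown <- setdiff(as.character(all_ids), names(table$reputation))
  if (length(unknown)) stop_param("unknown participant id: ",
                                  paste(unknown, collapse = ", "))
  for (id in as.character(events$plus %||% character()))
    table$reputation[id] <- table$reputation[id] + 1L
  for (id in as.character(events$minus %||% character()))
    table$reputation[id] <- max(0L, table$reputation[id] - 1L)
  newly <- names(table$reputation)[table$reputation == 0L]
  table$blacklist <- union(table$blacklist, newly)
  table
}

eligible_miners <- function(table) {
  ids <- names(table$reputation)
  ids[table$roles[ids] == "miner" & table$reputation > 0 &
        !(ids %in% table$blacklist)]
}

active_devices <- function(table) {
  ids <- names(table$reputation)
  ids[table$roles[ids] == "device" & !(ids %in% table$blacklist)]
}

# raw digest -> integer in [0, mod)
hash_mod <- function(digest, mod) {
  Reduce(function(a, b) (a * 256 + b) %% mod, as.integer(digest), 0)
}

#' Reputation-weighted committee selection by consistent hashing
#'
#' The eligible (non-blacklisted, positive-reputation) miners own
#' contiguous arcs on an integer hash ring, in ascending miner-id order,
#' with arc length equal to reputation (ring modulus = total reputation),
#' so selection probability is proportional to reputation by
#' construction.  Starting from the last block's hash, the digest is
#' repeatedly rehashed with SHA-256; each digest taken modulo the ring
#' size picks the miner owning that position, already-selected miners are
#' skipped, and rehashing continues until `M` distinct members are
#' found.  Fully deterministic given (hash, table, M).
#'
#' @param last_block_hash 32-byte raw digest of the latest block.
#' @param table a [reputation_table()].
#' @param M committee size; there must be at least `M` eligible miners.
#' @return character vector of `M` miner ids in selection order.
#' @export
select_committee <- function(last_block_hash, table, M) {
  miners <- sort(eligible_miners(table))
  if (length(miners) < M)
    stop_param("consensus error: only ", length(miners),
               " eligible miners for committee size ", M)
  reps <- as.numeric(table$reputation[miners])
  ends <- cumsum(reps)
  total <- ends[length(ends)]
  h <- as.raw(last_block_hash)
  chosen <- character()
  while (length(chosen) < M) {
    pos <- hash_mod(h, total)
    owner <- miners[which(pos < ends)[1]]
    if (!(owner %in% chosen)) chosen <- c(chosen, owner)
    h <- sha256_raw(h)
  }
  chosen
}

#' @describeIn select_committee deterministic leader pick:
#'   `SHA-256(last_block_hash || "leader") mod M` indexes the committee.
#' @param committee committee returned by `select_committee()`.
#' @export
select_leader <- function(committee, last_block_hash) {
  M <- length(committee)
  if (M < 1) stop_param("empty committee")
  h <- sha256_raw(c(as.raw(last_block_hash), charToRaw("leader")))
  committee[hash_mod(h, M) + 1]
}

# --- blocks ------------------------------------------------------------

# Canonical unsigned block bytes.  Field order: magic, round, prev_hash,
# is_empty, committee, transactions (device id, gradient, device
# signature, endorsements), leader id.
block_unsigned_bytes <- function(block) {
  out <- c(charToRaw("FCB1"), ser_u64(block$round),
           ser_bytes(block$prev_hash), ser_u64(as.integer(block$is_empty)),
           ser_u64(length(block$committee)))
  for (m in block$committee) out <- c(out, ser_string(m))
  out <- c(out, ser_u64(length(block$transactions)))
  for (tx in block$transactions) {
    out <- c(out, ser_string(tx$device_id), ser_doubles(tx$gradient),
             ser_bytes(tx$device_sig), ser_u64(length(tx$endorsements)))
    for (e in tx$endorsements)
      out <- c(out, ser_string(e$verifier), ser_bytes(e$sig))
  }
  c(out, ser_string(block$leader_id))
}

serialize_block <- function(block) {
  c(block_unsigned_bytes(block), ser_bytes(block$leader_sig))
}

deserialize_block <- function(bytes) {
  cur <- cursor(bytes)
  magic <- rawToChar(take(cur, 4))
  if (magic == "FCG1") return(deserialize_genesis_body(cur))
  if (magic != "FCB1") stop_param("bad block magic: ", magic)
  round <- rd_u64(cur)
  prev_hash <- rd_bytes(cur)
  is_empty <- rd_u64(cur) == 1
  committee <- vapply(seq_len(rd_u64(cur)), function(i) rd_string(cur), "")
  ntx <- rd_u64(cur)
  txs <- lapply(seq_len(ntx), function(i) {
    device_id <- rd_string(cur)
    gradient <- rd_doubles(cur)
    device_sig <- rd_bytes(cur)
    nend <- rd_u64(cur)
    ends <- lapply(seq_len(nend), function(j)
      list(verifier = rd_string(cur), sig = rd_bytes(cur)))
    list(device_id = device_id, gradient = gradient,
         device_sig = device_sig, endorsements = ends)
  })
  leader_id <- rd_string(cur)
  leader_sig <- rd_bytes(cur)
  blk <- list(round = round, prev_hash = prev_hash, is_empty = is_empty,
              committee = committee, transactions = txs,
              leader_id = leader_id, leader_sig = leader_sig)
  blk$hash <- sha256_raw(serialize_block(blk))
  class(blk) <- "fc_block"
  blk
}

# device transaction message = round || device id || gradient bytes
tx_message <- function(round, device_id, gradient) {
  c(ser_u64(round), ser_string(device_id), ser_doubles(gradient))
}

#' Assemble and sign one round's block
#'
#' The leader collects the accepted transactions, serializes the block
#' canonically, and signs the SHA-256 digest of the unsigned bytes.  An
#' empty `accepted` list produces a valid block with zero transactions.
#'
#' @param round round index (>= 1).
#' @param prev_hash digest of the predecessor block.
#' @param accepted list of transactions: each a list with `device_id`,
#'   `gradient`, `device_sig`, `endorsements`.
#' @param committee the round's committee ids (stored for audit).
#' @param leader_id the leader, a committee member.
#' @param keys keyring with the leader's key.
#' @param is_empty mark the block as the round's empty fallback.
#' @return object of class `fc_block` (with its `hash`).
#' @export
build_block <- function(round, prev_hash, accepted, committee, leader_id,
                        keys, is_empty = length(accepted) == 0) {
  blk <- list(round = round, prev_hash = as.raw(prev_hash),
              is_empty = is_empty, committee = committee,
              transactions = accepted, leader_id = leader_id)
  blk$leader_sig <- sign_bytes(keys, leader_id,
                               sha256_raw(block_unsigned_bytes(blk)))
  blk$hash <- sha256_raw(serialize_block(blk))
  class(blk) <- "fc_block"
  blk
}

# per-verifier block check used both in consensus and in the audit
block_checks_out <- function(block, keys, M) {
  ok_leader <- verify_bytes(keys, block$leader_id,
                            sha256_raw(block_unsigned_bytes(block)),
                            block$leader_sig) &&
    block$leader_id %in% block$committee
  if (!ok_leader) return(FALSE)
  for (tx in block$transactions) {
    if (!verify_bytes(keys, tx$device_id,
                      tx_message(block$round, tx$device_id, tx$gradient),
                      tx$device_sig)) return(FALSE)
    msg <- ser_doubles(tx$gradient)
    valid <- vapply(tx$endorsements, function(e)
      verify_bytes(keys, e$verifier, msg, e$sig) &&
        e$verifier %in% block$committee, TRUE)
    if (sum(valid) <= M / 2) return(FALSE)
  }
  TRUE
}

#' Committee approval of a candidate block
#'
#' Each honest verifier checks the leader's signature, every
#' transaction's device signature, and every endorsement majority, and
#' votes to approve only if all checks pass; malicious verifiers vote to
#' reject regardless.  The block is valid only when strictly more than
#' 2/3 of the committee approves; otherwise the round falls back to an
#' empty block (correct `prev_hash`, no transactions) so the chain never
#' stalls.
#'
#' @param block candidate `fc_block`.
#' @param committee the round's committee.
#' @param keys keyring.
#' @param malicious_verifiers committee members voting reject.
#' @return list with `valid` (logical), `approvals` (count), and `block`
#'   (the input block if valid, else the empty fallback block signed by
#'   the same leader).
#' @export
approve_block <- function(block, committee, keys,
                          malicious_verifiers = character()) {
  M <- length(committee)
  honest_ok <- block_checks_out(block, keys, M)
  votes <- vapply(committee, function(v) {
    if (as.character(v) %in% as.character(malicious_verifiers)) FALSE
    else honest_ok
  }, TRUE)
  approvals <- sum(votes)
  if (approvals > 2 * M / 3)
    return(list(valid = TRUE, approvals = approvals, block = block))
  empty <- build_block(block$round, block$prev_hash, list(), committee,
                       block$leader_id, keys, is_empty = TRUE)
  list(valid = FALSE, approvals = approvals, block = empty)
}

# --- genesis -----------------------------------------------------------

#' Genesis block
#'
#' Round 0 of the chain: the initial model parameters, the total round
#' budget `T`, every party's public key, the initial reputation of every
#' party, and the reputation-rule identifier.
#'
#' @param w0 initial `model_params`.
#' @param total_rounds maximum training rounds `T`.
#' @param keys keyring of all parties.
#' @param table initial [reputation_table()].
#' @param rule_id reputation update rule identifier.
#' @return object of class `fc_block` (round 0).
#' @export
build_genesis <- function(w0, total_rounds, keys, table,
                          rule_id = "plus1-qualified/minus1-rejected/blacklist-at-0") {
  ids <- names(table$reputation)
  out <- c(charToRaw("FCG1"), ser_u64(0), ser_bytes(raw(32)),
           ser_u64(total_rounds), ser_string(w0$arch_id),
           ser_doubles(w0$values), ser_u64(length(ids)))
  for (id in ids)
    out <- c(out, ser_string(id), ser_string(table$roles[id]),
             ser_bytes(public_key(keys, id)),
             ser_u64(table$reputation[id]))
  out <- c(out, ser_string(rule_id))
  blk <- list(round = 0, prev_hash = raw(32), is_empty = FALSE,
              committee = character(), transactions = list(),
              leader_id = "", leader_sig = raw(0),
              genesis = list(total_rounds = total_rounds,
                             arch_id = w0$arch_id, w0 = w0$values,
                             parties = ids, rule_id = rule_id),
              bytes = out, hash = sha256_raw(out))
  class(blk) <- "fc_block"
  blk
}

deserialize_genesis_body <- function(cur) {
  round <- rd_u64(cur)
  prev <- rd_bytes(cur)
  total_rounds <- rd_u64(cur)
  arch_id <- rd_string(cur)
  w0 <- rd_doubles(cur)
  n <- rd_u64(cur)
  parties <- character(n); roles <- character(n); reps <- integer(n)
  pks <- vector("list", n)
  for (i in seq_len(n)) {
    parties[i] <- rd_string(cur); roles[i] <- rd_string(cur)
    pks[[i]] <- rd_bytes(cur);   reps[i] <- rd_u64(cur)
  }
  rule_id <- rd_string(cur)
  bytes <- cur$bytes
  blk <- list(round = round, prev_hash = prev, is_empty = FALSE,
              committee = character(), transactions = list(),
              leader_id = "", leader_sig = raw(0),
              genesis = list(total_rounds = total_rounds,
                             arch_id = arch_id, w0 = w0,
                             parties = parties, rule_id = rule_id),
              bytes = bytes, hash = sha256_raw(bytes))
  class(blk) <- "fc_block"
  blk
}

block_bytes <- function(block) {
  if (!is.null(block$genesis)) block$bytes else serialize_block(block)
}

#' @export
print.fc_block <- function(x, ...) {
  kind <- if (!is.null(x$genesis)) "genesis"
          else if (x$is_empty) "empty" else "block"
  cat(sprintf("<fc_block %s> round=%d tx=%d hash=%s...\n", kind, x$round,
              length(x$transactions),
              paste(format(x$hash[1:6]), collapse = "")))
  invisible(x)
}

# --- chain audit and persistence ---------------------------------------

#' Re-verify a completed chain
#'
#' Walks the chain from genesis: every block's `prev_hash` must equal the
#' SHA-256 digest of its predecessor's canonical bytes, every leader
#' signature must verify against a committee member's key, and every
#' stored transaction must carry a strict-majority endorsement with valid
#' signatures.  Returns `TRUE` invisibly or stops with the first
#' violation.
#'
#' @param chain list of `fc_block`s, genesis first.
#' @param keys keyring of all parties.
#' @return TRUE (invisibly) if the audit passes.
#' @export
audit_chain <- function(chain, keys) {
  if (length(chain) == 0) stop_param("empty chain")
  if (is.null(chain[[1]]$genesis)) stop_param("chain must start at genesis")
  for (i in seq_along(chain)) {
    blk <- chain[[i]]
    if (i == 1) next
    prev <- chain[[i - 1]]
    if (!identical(as.raw(blk$prev_hash),
                   as.raw(sha256_raw(block_bytes(prev)))))
      stop_param("audit: hash link broken at round ", blk$round)
    if (!block_checks_out(blk, keys, length(blk$committee)))
      stop_param("audit: invalid signatures/endorsements at round ",
                 blk$round)
  }
  invisible(TRUE)
}

#' Persist or reload a chain
#'
#' `write_chain()` stores each block's canonical bytes as a
#' length-prefixed binary file (`blk_00000.bin`, ...) plus a JSON index
#' with round numbers and hex digests; `read_chain()` reloads and
#' re-parses them (recomputing each hash from the stored bytes, so any
#' tampering surfaces in [audit_chain()]).
#'
#' @param chain list of `fc_block`s.
#' @param dir directory to create/use.
#' @return `read_chain()` returns the list of blocks.
#' @export
write_chain <- function(chain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(chain))
  for (i in seq_along(chain)) {
    b <- block_bytes(chain[[i]])
    files[i] <- sprintf("blk_%05d.bin", chain[[i]]$round)
    con <- file(file.path(dir, files[i]), "wb")
    writeBin(c(ser_u64(length(b)), b), con)
    close(con)
  }
  idx <- list(blocks = data.frame(
    round = vapply(chain, function(b) b$round, 0),
    file = files,
    hash = vapply(chain, function(b) paste(format(b$hash), collapse = ""),
                  ""),
    stringsAsFactors = FALSE))
  jsonlite::write_json(idx, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_chain
#' @export
read_chain <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  ord <- order(idx$blocks$round)
  lapply(ord, function(i) {
    path <- file.path(dir, idx$blocks$file[i])
    bytes <- readBin(path, "raw", n = file.size(path))
    cur <- cursor(bytes)
    deserialize_block(rd_bytes(cur))
  })
}
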