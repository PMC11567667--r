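# Shared fixtures: all built in code, no data files.

default_pool <- function(n = 100) synthetic_object_pool(n)

two_session_sets <- function(seed = 11) {
  pool <- default_pool()
  list(build_sequence_set("remote", pool[1:30, ], seed = seed),
       build_sequence_set("recent", pool[31:60, ], seed = seed + 1))
}

# minimal hand-built sequence set (1 sequence + 1 baseline) for toy cases
# that the constrained builder cannot produce
toy_sequence_set <- function(session = "remote", prefix = session) {
  sequences <- tibble::tibble(
    sequence_id = 1L,
    A = paste0(prefix, "_A1"), B = paste0(prefix, "_B1"),
    C1 = paste0(prefix, "_C1x"), C2 = paste0(prefix, "_C2x"),
    c_bin = "big")
  objects <- tibble::tibble(
    object_id = c(sequences$A, sequences$B, sequences$C1, sequences$C2,
                  paste0(prefix, "_base1")),
    role = c("A", "B", "C1", "C2", "baseline"),
    sequence_id = c(1L, 1L, 1L, 1L, NA),
    session = session,
    size_bin = c("small", "small", "big", "big", "big"))
  structure(list(session = session, sequences = sequences, objects = objects),
            class = "sequence_set")
}

# tiny pattern matrices with rownames, for similarity toys
named_patterns <- function(m, prefix = "p") {
  rownames(m) <- paste0(prefix, seq_len(nrow(m)))
  m
}
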