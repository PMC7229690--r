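# Shared model fixtures.  Threshold caches live inside the objects, so
# reusing these across tests avoids recomputing the recursion.

m_strong <- decision_model(4, rho = 0.9, eps = 1)          # strongly aligned
m_weak   <- decision_model(4, rho = 0.5, eps = 1)          # weakly aligned
m_indep  <- decision_model(4, rho = 0, eps = 1)            # uncorrelated
m_ident  <- decision_model(4, rho = 1, eps = 1)            # identical prefs

s_equal  <- subtype_decision_model(4, gamma = 0.5, rho_high = 1,
                                   rho_low = 0, eps = 0.25)     # two equal types
s_major  <- subtype_decision_model(4, gamma = 0.9, rho_high = 0.9,
                                   rho_low = 0.25, eps = 0.5)   # 90/10 split

histories_upto <- function(n) {
  unlist(lapply(seq_len(n), function(m) {
    g <- expand.grid(rep(list(c("A", "B")), m), stringsAsFactors = FALSE)
    apply(g[, rev(seq_len(m)), drop = FALSE], 1, paste, collapse = "")
  }))
}
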