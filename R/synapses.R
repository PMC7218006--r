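#' Kinetic constants of the chemical synapse classes
#'
#' First-order transmitter-binding kinetics `d[R]/dt = bind*[T]*(1-[R]) -
#' unbind*[R]`, with `[T] = 0.5` mM during a transmitter pulse and 0
#' otherwise. GABA-B adds G-protein accumulation `d[G]/dt = 0.18[R] -
#' 0.034[G]` and a 4th-order Hill activation `[G]^4/([G]^4 + 100)` of its
#' conductance. Pulse durations depend on the presynaptic cell type.
#'
#' @param kind `"AMPA"`, `"GABA_A"` or `"GABA_B"`.
#' @return named list: `bind`, `unbind` (1/(mM ms), 1/ms), `e_rev` (mV) and
#'   per-presynaptic-type pulse durations (ms).
#' @export
synapse_rates <- function(kind = c("AMPA", "GABA_A", "GABA_B")) {
  kind <- match.arg(kind)
  switch(kind,
    AMPA   = list(bind = 0.98, unbind = 0.18, e_rev = 0,
                  pulse = c(HTC = 0.3, TC = 0.5)),
    GABA_A = list(bind = 20, unbind = 0.18, e_rev = -85,
                  pulse = c(HTC = 1.0, RE = 0.3)),
    GABA_B = list(bind = 0.09, unbind = 0.0012, e_rev = -95,
                  pulse = c(RE = 0.3))
  )
}

#' Steady-state bound-receptor fraction under sustained transmitter
#'
#' Fixed point of the binding kinetics: `bind*T / (bind*T + unbind)`.
#'
#' @param kind synapse class, see [synapse_rates()].
#' @param transmitter sustained transmitter concentration (mM).
#' @return fraction in `[0, 1)`.
#' @export
synapse_fixed_point <- function(kind = "AMPA", transmitter = 0.5) {
  k <- synapse_rates(kind)
  k$bind * transmitter / (k$bind * transmitter + k$unbind)
}

#' GABA-B Hill activation of the conductance
#'
#' @param g_protein G-protein concentration `[G]`.
#' @return `[G]^4 / ([G]^4 + 100)`.
#' @export
gabab_hill <- function(g_protein) g_protein^4 / (g_protein^4 + 100)

#' Gap-junction current
#'
#' Ohmic electrical coupling `I = g * (v_self - v_other)`; antisymmetric
#' between the coupled pair, so pairwise charge is conserved.
#'
#' @param v_self,v_other membrane voltages (mV).
#' @param g_gj coupling conductance (mS/cm^2).
#' @return current density (uA/cm^2) leaving `self`.
#' @export
gap_current <- function(v_self, v_other, g_gj = 0.004) {
  if (!all(is.finite(c(v_self, v_other)))) abort("voltages must be finite")
  g_gj * (v_self - v_other)
}

#' Cholinergic modulation of the HTC potassium leak
#'
#' Muscarinic ACh receptor activation is modelled as a fractional reduction of
#' the HTC potassium-leak conductance: `eta_ach = 100 * (g_norm - g_mod) /
#' g_norm` (%), so `apply_ach()` returns `g_mod = g_norm * (1 - eta/100)`.
#' Negative `eta_ach` (cholinergic tone below normal) increases the leak.
#'
#' @param eta_ach cholinergic-tone index (%), `< 100`.
#' @param g_kleak_norm normal potassium-leak conductance (mS/cm^2).
#' @param g_kleak_mod modified conductance, for the inverse mapping.
#' @return modified conductance (mS/cm^2), or `eta` in %.
#' @examples
#' apply_ach(20, 0.01)        # 0.008
#' eta_from_gkleak(0.008, 0.01)  # 20
#' @export
apply_ach <- function(eta_ach, g_kleak_norm = 0.01) {
  if (g_kleak_norm <= 0) abort("`g_kleak_norm` must be > 0")
  if (any(eta_ach > 100)) abort("eta_ach > 100% would give a negative conductance")
  g_kleak_norm * (1 - eta_ach / 100)
}

#' @rdname apply_ach
#' @export
eta_from_gkleak <- function(g_kleak_mod, g_kleak_norm = 0.01) {
  if (g_kleak_norm <= 0) abort("`g_kleak_norm` must be > 0")
  100 * (g_kleak_norm - g_kleak_mod) / g_kleak_norm
}

#' Build the thalamic network topology
#'
#' The scaled-down motif: `n_htc` HTC pacemaker cells (20% of the
#' thalamocortical population), four relay TC cells per HTC, and one RE cell
#' per thalamocortical cell (RE:TC ratio 1:1). Connection classes, all-to-all
#' between the populations involved (conductances in mS/cm^2):
#'
#' * HTC -> RE: AMPA 0.001; TC -> RE: AMPA 0.05
#' * HTC -> TC: GABA-A 0.4 with a 10-ms delay (implicit inhibitory
#'   interneuron relay)
#' * RE -> HTC: GABA-A 0.0002 and GABA-B 0.004
#' * RE -> TC: GABA-A 0.002 and GABA-B 0.004
#' * RE -> RE: GABA-A 0.02 (no self-connection)
#' * HTC-HTC gap junctions (all pairs), `g_gj` default 0.004
#'
#' TC cells contact no other TC cells and no HTC cells. Each connection keeps
#' its own receptor state.
#'
#' @param n_htc number of HTC cells (>= 2; default 2 gives the 2/8/10 motif).
#' @param g_gj gap-junction conductance (mS/cm^2).
#' @param conductances named overrides of the class conductances, e.g.
#'   `c(htc_tc_gabaa = 0)` to cut the delayed HTC -> TC inhibition. Names:
#'   `htc_re_ampa, tc_re_ampa, htc_tc_gabaa, re_htc_gabaa, re_htc_gabab,
#'   re_tc_gabaa, re_tc_gabab, re_re_gabaa`.
#' @return a list of class `thal_topology`: counts, a `synapses` tibble (one
#'   row per connection: `pre`, `post` 1-based cell indices, `kind`, `g_max`,
#'   `e_rev`, `bind`, `unbind`, `pulse`, `delay`) and a `gap_junctions`
#'   tibble. Cell order: HTC, then TC, then RE.
#' @examples
#' net <- build_network()
#' table(net$synapses$class)
#' @export
build_network <- function(n_htc = 2, g_gj = 0.004, conductances = NULL) {
  if (n_htc < 2) abort("`n_htc` must be >= 2 (gap-junction pairing)")
  n_tc <- 4 * n_htc            # 20% of thalamocortical cells are HTC
  n_re <- n_htc + n_tc         # RE:TC ratio 1:1
  gdef <- c(htc_re_ampa = 0.001, tc_re_ampa = 0.05, htc_tc_gabaa = 0.4,
            re_htc_gabaa = 0.0002, re_htc_gabab = 0.004,
            re_tc_gabaa = 0.002, re_tc_gabab = 0.004, re_re_gabaa = 0.02)
  if (!is.null(conductances)) {
    bad <- setdiff(names(conductances), names(gdef))
    if (length(bad)) abort(paste("unknown connection class:", paste(bad, collapse = ", ")))
    gdef[names(conductances)] <- conductances
  }
  htc <- seq_len(n_htc)
  tc <- n_htc + seq_len(n_tc)
  re <- n_htc + n_tc + seq_len(n_re)

  pairs <- function(pre, post, class, kind, g, delay = 0, self = FALSE) {
    grid <- expand.grid(pre = pre, post = post)
    if (!self) grid <- grid[grid$pre != grid$post, ]
    k <- synapse_rates(kind)
    pre_type <- if (all(pre %in% htc)) "HTC" else if (all(pre %in% tc)) "TC" else "RE"
    tibble(class = class, pre = grid$pre, post = grid$post, kind = kind,
           g_max = g, e_rev = k$e_rev, bind = k$bind, unbind = k$unbind,
           pulse = unname(k$pulse[pre_type]), delay = delay)
  }
  syn <- bind_rows(
    pairs(htc, re, "htc_re_ampa", "AMPA", gdef[["htc_re_ampa"]]),
    pairs(tc, re, "tc_re_ampa", "AMPA", gdef[["tc_re_ampa"]]),
    pairs(htc, tc, "htc_tc_gabaa", "GABA_A", gdef[["htc_tc_gabaa"]], delay = 10),
    pairs(re, htc, "re_htc_gabaa", "GABA_A", gdef[["re_htc_gabaa"]]),
    pairs(re, htc, "re_htc_gabab", "GABA_B", gdef[["re_htc_gabab"]]),
    pairs(re, tc, "re_tc_gabaa", "GABA_A", gdef[["re_tc_gabaa"]]),
    pairs(re, tc, "re_tc_gabab", "GABA_B", gdef[["re_tc_gabab"]]),
    pairs(re, re, "re_re_gabaa", "GABA_A", gdef[["re_re_gabaa"]])
  )
  gj <- expand.grid(a = htc, b = htc)
  gj <- gj[gj$a < gj$b, ]
  gap <- tibble(a = gj$a, b = gj$b, g_gj = g_gj)
  structure(list(n_htc = n_htc, n_tc = n_tc, n_re = n_re,
                 synapses = syn, gap_junctions = gap),
            class = "thal_topology")
}

#' @export
print.thal_topology <- function(x, ...) {
  cat("<thal_topology> ", x$n_htc, " HTC / ", x$n_tc, " TC / ", x$n_re,
      " RE cells, ", nrow(x$synapses), " synapses, ",
      nrow(x$gap_junctions), " gap junction(s)\n", sep = "")
  invisible(x)
}
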