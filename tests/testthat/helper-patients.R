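# Shared fixtures: small, fast virtual patients built in code.

# a homogeneous open lung: n identical compartments, no collapse
uniform_lung <- function(n = 50, k = 2.5, raw = 1, top = 0.5, d_close = 0.4) {
  compartment_params(k = rep(k, n), k3 = 0, p_ext = 0, top = top,
                     d_close = d_close, r_aw = raw, r_vasc = 1, tau_c = 0)
}

# a moderate-ARDS test patient, smaller than the reference 100
# compartments so engine-level tests stay fast
test_patient <- function(n = 50, collapsed = 0.25, seed = 7, ...) {
  # per-compartment stiffness scales with n so total lung compliance (and
  # hence tidal volume against the fixed 150 ml dead space) stays realistic
  virtual_patient(
    hyper = utils::modifyList(list(collapsed_frac = collapsed,
                                   k_mean = 2.4 * n / 100,
                                   raw_mean = n / 100,
                                   cd = 0.8, q_grad = 0.3,
                                   tau_logmean = log(20)), list(...)),
    metabolic = list(hb = 10.5, co = 8, vo2 = 250, rq = 0.7, fio2 = 0.8),
    vent = list(vr = 14, ie = 0.33),
    label = "test", n = n, seed = seed)
}

# short protocol helpers (minutes compressed for test speed)
short_baseline <- function(patient, peep = 10, minutes = 2) {
  ardsim:::new_protocol(list(build_baseline(peep, minutes * 60, patient)),
                        "baseline")
}
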