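# Default pipeline configuration for tdregimes::run_pipeline().
# Any key may be omitted; package defaults then apply.

# Curve-shape scenario: APHP (average peak ~34 DIM, persistent tail) or
# HPLP (higher peak ~35 DIM, faster decline).
scenario: APHP

# Synthetic paternal half-sib pedigree: founder sires and recorded cows.
n_sires: 82
n_dams: 464

# Days from calving to dry-off; daily yields are simulated on 1..L.
lactation_length: 280

# Variance components for the Wood parameter triples (k, b, c).
# G: upper triangle (column-major: g11, g12, g22, g13, g23, g33) of the
#    genetic covariance; E_diag: environmental variances (covariances are
#    zero); sigma_eps2: residual variance of daily yield in kg^2.
# Omit the whole block to use the shipped calibrated defaults
# (realized h2 of 280-day yield = 0.2 under APHP).
#varcomps:
#  G: [9.70e-3, -1.42e-3, 1.30e-3, -2.67e-5, 2.28e-5, 8.15e-7]
#  E_diag: [0.0121, 0.0016, 0.000001]
#  sigma_eps2: 1.44

# Equally spaced recording schedules to score (weekly = 40 TD, monthly =
# 10 TD, quarterly = 4 TD).
schedules: [weekly, monthly, quarterly]

# Pool-elimination search: m test days per regime, number of loops, and
# the per-day coverage requirement (regimes containing each pool day).
m: 4
loops: 10
coverage: 25

# Genetic evaluation and planning.
h2: 0.2                  # heritability used in BLUP and Eq.-style planning
top_k: 100               # size of the selected group for ranking agreement
qualify_threshold: 80    # regimes need MORE than this Top-k overlap
reliability_target: 0.5  # sire reliability the planning table aims for
budget: 7500             # total test-day records (30 farms x 25 cows x 10)

# Master seed; every stage derives a named substream from it.
seed: 1
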