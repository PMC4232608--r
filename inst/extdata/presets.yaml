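# Generator presets for the synthetic-data module.
#
# Each top-level key is a generator family; entries under it are named
# presets.  A "common" entry holds family-wide defaults merged into every
# preset of that family.  Genotype-level numbers (propagation
# probabilities, cap ratios, enrichment amplitudes, decay rates, step
# SDs, retention fidelities) are the published point estimates for the
# corresponding strains; purely instrumental parameters (pixel size,
# noise, PSF) are documented choices (see the methods vignette).
schema_version: 1

segregation:
  common:
    count_mix: [0.61, 0.33, 0.06]   # observed 1/2/4-focus proportions
  wt:        {p_prop: 0.039}
  gcn5:      {p_prop: 0.111}
  gcn5_E173A: {p_prop: 0.110}
  spt3:      {p_prop: 0.097}
  sgf73:     {p_prop: 0.118}
  sac3:      {p_prop: 0.115}
  sus1:      {p_prop: 0.113}
  bud6:      {p_prop: 0.118}
  yku70:     {p_prop: 0.103}
  gcn5_tetr: {p_prop: 0.011}

nucleus:
  common:
    pixel_size: 0.065        # um per pixel (100x objective, 1x1 binning)
    img_px: 72               # square image side, pixels
    radius_um: 1.0           # nuclear rim radius
    psf_sd_um: 0.25          # radial Gaussian blur SD of the rim annulus
    trunc_sd: 3              # annulus truncated at this many SDs
    cap_span: 1.5707963      # angular width of the NPC cap (rad)
    background: 10           # counts per pixel
    gain: 1.0                # photon gain for Poisson shot noise
    read_sd: 2.0             # additive Gaussian read noise SD (counts)
    cap_cv: 0.25             # per-cell lognormal CV of the cap ratio
    photon_cv: 0.25          # per-cell lognormal CV of the photon budget
    focus_photons: 3000      # red-channel plasmid focus photons
    focus_sd_um: 0.15        # red-channel focus PSF SD
  wt_loaded:   {cap_ratio: 2.02, total_photons: 54000}  # 2.7x unloaded
  bud6_loaded: {cap_ratio: 2.29, total_photons: 54000}
  unloaded:    {cap_ratio: 1.00, total_photons: 20000}

division:
  common:
    logit_sd: 0.25           # per-cell spread of mother share (logit scale)
    total_mean: 5000         # integrated fluorescence per division (A.U.)
    total_cv: 0.30
    max_age: 30
  wt_loaded:    {pct_mother_median: 78}
  unloaded:     {pct_mother_median: 63}
  gcn5_loaded:  {pct_mother_median: 63}
  sgf73_loaded: {pct_mother_median: 63}

rim:
  common:
    radius_um: 1.0
    step_um: 0.05            # arc sampling step (<= 65 nm)
    window_um: 0.130         # half-width of the co-localization window
    bump_sd_um: 0.065        # SD of the truncated Gaussian enrichment bump
    noise_sd: 0.12           # AR(1) innovation SD on the green channel
    noise_ar: 0.5
    red_peak_sd_um: 0.10     # red-channel plasmid peak SD
    red_noise_sd: 0.03
  wt:   {amplitude: 0.332}
  gcn5: {amplitude: 0.046}
  sus1: {amplitude: -0.020}
  flat: {amplitude: 0.0}

flip:
  common:
    interval_s: 9.0          # bleach/acquisition interval
    n_points: 30
    I0: 100.0
    immobile_frac: 0.0
    noise_sd: 0.0
    acq_loss_per_frame: 0.0  # additive per-frame acquisition loss (A.U.)
  circle_adjacent: {k_decay: 0.0043496936}  # ln(10/7)/82 s^-1
  opposite:        {k_decay: 0.0142669949}  # ln(10/7)/25 s^-1
  whole_wt:        {k_decay: 0.0198042052}  # ln(2)/35 s^-1
  whole_gcn5:      {k_decay: 0.0150683431}  # ln(2)/46 s^-1
  whole_sgf73:     {k_decay: 0.0169059703}  # ln(2)/41 s^-1
  barrier_wt:      {k_mother: 0.020, k_bud: 0.0066667, noise_sd: 1.5}
  barrier_bud6:    {k_mother: 0.020, k_bud: 0.020,     noise_sd: 1.5}

frap:
  common:
    interval_s: 3.0
    n_points: 61
    noise_sd: 0.0
  default:        {k: 0.0325, plateau: 100}
  stable_pore:    {k: 0.005,  plateau: 60, noise_sd: 1.0}
  shuttling_pore: {k: 0.050,  plateau: 80, noise_sd: 1.0}

tracks:
  common:
    dt_s: 3.0
    n_points: 61             # 3 s steps for 3 min
    confine_um: 1.0          # reflecting confinement radius (0 = none)
  wt:   {step_sd_um: 0.0939984}   # chi(3): E|step| = 0.15 um -> 0.05 um/s
  gcn5: {step_sd_um: 0.1691972}   # E|step| = 0.27 um -> 0.09 um/s

pedigree:
  common:
    k_circles: 24            # per-mother circle count (calibration knob)
  wt:    {p_prop: 0.039}
  gcn5:  {p_prop: 0.111}
  sgf73: {p_prop: 0.118}

sectors:
  wt:   {p_excise: 0.010, p_first_loss: 0.5}
  sir2: {p_excise: 0.030, p_first_loss: 0.5}
  fob1: {p_excise: 0.001, p_first_loss: 0.5}

ageing:
  common:
    T_death: 64              # circle-count death threshold
    s0: 0.63                 # baseline NPC mother share, no circles
    kappa: 0.01              # pore-pool fraction bound per circle
    b_max: 0.4166667         # saturation of the bound fraction
    fidelity: 0.99           # retention of circle-bound pores
    npc_growth: 0.6          # per-division fractional pore synthesis
    npc0: 100.0              # pore fluorescence at birth (A.U.)
    max_gen: 150
  wt:    {rho: 0.961, f_form: 0.030}
  gcn5:  {rho: 0.889, f_form: 0.045}
  sgf73: {rho: 0.882, f_form: 0.015}
  bud6:  {rho: 0.882, f_form: 0.030}
  fob1:  {rho: 0.961, f_form: 0.003}
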