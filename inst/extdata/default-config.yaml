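# Default constants and parameters for twistcouple.
# Every value here can be overridden by passing a modified copy of this
# file to load_config(); functions take the resulting pieces as arguments.

physical_context:
  temperature: 295          # K; working temperature of the reference ensembles
  dielectric_constant: 78.4 # relative permittivity of water
  reference_salt: 1.0       # M; twist changes are defined as zero here

electrostatics:
  pp_distance: 0.6          # nm; phosphate-phosphate distance across the major groove
  rescale_alpha: 1.8        # dimensionless; absorbs many-pair P-P repulsions into
                            # the single-pair force estimate

entropy:
  k_SG: 0.024               # kJ/(mol K nm); slope of conformational entropy vs
                            # major groove width (== kJ/(mol degC nm))

geometry:
  diameter: 1.95            # nm; A-form duplex diameter
  inclination: 16.5         # deg; base-pair inclination (midpoint of 15.5-17.5)
  strand_azimuth: 140       # deg; azimuthal angle between the two strands
  # rise (nm/bp) is calibrated so the geometric relation passes through the
  # reference equilibrium point (32.15 deg, 0.52 nm); pass an explicit value
  # to geometry_params() to override.

pmf:
  twist_bin: 0.1            # deg; default 2-D histogram bin width for twist
  conj_bin: 0.01            # nm; default bin width for the conjugate coordinate
  cutoff: 3.0               # kBT; quadratic surface fitted to bins below this

tweezers:
  n_bp_tether: 13600        # base pairs of the duplex in the rotation assay
  apex_exclusion: 5         # turns; flat peak region excluded from line fits
  window_span: 20           # turns; outer reach of the plectoneme fit windows

presets:
  rna-eq3:                  # fitted A-RNA twist - major-groove-width coupling
    k_omega: 0.18           # kBT/deg^2 per bp; twist stiffness
    k_conj: 3.61            # kBT/nm^2 per bp; groove-width modulus
    k_cross: 0.43           # kBT/(deg nm) per bp; twist-groove cross coupling
    omega0: 32.15           # deg; equilibrium twist at 1 M and 295 K
    conj0: 0.52             # nm; equilibrium major groove width
    coordinate_label: groove_width
    n_bp: 19                # central base pairs averaged per snapshot
  dna-prev:                 # B-DNA twist - diameter coupling
    k_omega: 0.18           # kBT/deg^2 per bp
    k_conj: 263.0           # kBT/nm^2 per bp; diameter modulus
    k_cross: 4.5            # kBT/(deg nm) per bp; twist-diameter coupling
    omega0: 34.3            # deg; canonical B-DNA twist (reference point only)
    conj0: 2.0              # nm; canonical B-DNA diameter (reference point only)
    coordinate_label: diameter
    n_bp: 19
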