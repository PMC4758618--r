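# Versioned library of simulation presets.
#
# Each preset plants per-genotype observable effect sizes as ground truth:
# "intensity" presets set the fold-change of integrated focus brightness
# (focus width at control value); "morphometry" presets set fold-changes of
# the fitted marginal peak height and FWHM. Arm CVs are the per-focus
# lognormal coefficients of variation (sd/mean of the corresponding
# published population). The first arm (or, for dual-tag presets, the
# single-tag arm of each channel) is the normalization reference.
version: 1
defaults:
  n_foci: 150
  baseline_photons: 5000
presets:
  wt_reference:
    mode: intensity
    channels: [GFP]
    source: "control definition: all folds 1"
    arms:
      - {genotype: wild_type, intensity_fold: 1.0, cv: 0.25}
  fig2a_psh1del:
    mode: intensity
    channels: [GFP]
    source: "Cse4-GFP wild type 1.00+/-0.25, psh1del 1.83+/-0.57"
    arms:
      - {genotype: wild_type, intensity_fold: 1.0, cv: 0.25}
      - {genotype: psh1del, intensity_fold: 1.83, cv: 0.31147541}  # 0.57/1.83
  fig2c_psh1del:
    mode: intensity
    channels: [GFP]
    source: "Mif2-GFP wild type 1.00+/-0.18, psh1del 1.35+/-0.25"
    arms:
      - {genotype: wild_type, intensity_fold: 1.0, cv: 0.18}
      - {genotype: psh1del, intensity_fold: 1.35, cv: 0.18518519}  # 0.25/1.35
  fig3c_psh1del:
    mode: morphometry
    channels: [GFP]
    source: >-
      Cse4-GFP peak height wild type 1.00+/-0.22, psh1del 1.71+/-0.53;
      FWHM wild type 1.00+/-0.23, psh1del 1.16+/-0.32
    arms:
      - {genotype: wild_type, peak_height_fold: 1.0, ph_cv: 0.22,
         fwhm_fold: 1.0, fwhm_cv: 0.23}
      - {genotype: psh1del, peak_height_fold: 1.71, ph_cv: 0.30994152,  # 0.53/1.71
         fwhm_fold: 1.16, fwhm_cv: 0.27586207}                         # 0.32/1.16
  fig4d_psh1del_ubr2del:
    mode: intensity
    channels: [CFP]
    source: >-
      Mtw1-CFP wild type 1.00+/-0.14, psh1del 1.04+/-0.13,
      ubr2del 1.05+/-0.16, psh1del ubr2del 1.28+/-0.21
    arms:
      - {genotype: wild_type, intensity_fold: 1.0, cv: 0.14}
      - {genotype: psh1del, intensity_fold: 1.04, cv: 0.125}        # 0.13/1.04
      - {genotype: ubr2del, intensity_fold: 1.05, cv: 0.15238095}   # 0.16/1.05
      - {genotype: psh1del_ubr2del, intensity_fold: 1.28, cv: 0.1640625}  # 0.21/1.28
  fig5b_dsn1dd:
    mode: intensity
    channels: [YFP]
    source: >-
      Mtw1-YFP in dsn1-S240D/S250D background: PSH1 UBR2 1.00+/-0.15,
      psh1del 1.08+/-0.16, ubr2del 1.19+/-0.24, psh1del ubr2del 1.48+/-0.27
    arms:
      - {genotype: wild_type, intensity_fold: 1.0, cv: 0.15}
      - {genotype: psh1del, intensity_fold: 1.08, cv: 0.14814815}   # 0.16/1.08
      - {genotype: ubr2del, intensity_fold: 1.19, cv: 0.20168067}   # 0.24/1.19
      - {genotype: psh1del_ubr2del, intensity_fold: 1.48, cv: 0.18243243}  # 0.27/1.48
  fig1b_dualtag:
    mode: intensity
    channels: [YFP, CFP]
    source: >-
      Dual-tag Mtw1 competition: endogenous YFP + ectopic CFP foci carry
      approximately 50% of the haploid YFP and 50% of the haploid CFP
      signal; haploid single-tag strains are the per-channel references.
      Per-focus cv 0.20 (chosen; panel shows error bars, not population sd).
    arms:
      - {genotype: haploid_yfp, intensity_fold: 1.0, cv: 0.20,
         frac_YFP: 1.0, frac_CFP: 0.0}
      - {genotype: haploid_cfp, intensity_fold: 1.0, cv: 0.20,
         frac_YFP: 0.0, frac_CFP: 1.0}
      - {genotype: dual_tag, intensity_fold: 1.0, cv: 0.20,
         frac_YFP: 0.5, frac_CFP: 0.5}
  fig1d_diploid:
    mode: intensity
    channels: [YFP]
    source: >-
      Ploidy scaling of Mtw1-YFP: diploid kinetochore clusters carry
      approximately double the haploid signal (fold 2.0; cv 0.20 chosen).
    arms:
      - {genotype: haploid, intensity_fold: 1.0, cv: 0.20}
      - {genotype: diploid, intensity_fold: 2.0, cv: 0.20}
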