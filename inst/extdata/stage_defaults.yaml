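# Representative stage parameters for an Anopheles gambiae population model.
# These are NOT a published life table: they are editable placeholder values
# chosen to give a plausible egg-to-pupa development time (~10-11 days) and a
# modestly growing population at low density.  Substitute literature values
# (durations in days, daily survival probabilities) to reproduce analyses
# tied to a specific cited life table.
stages:
  - name: egg
    duration_days: 2
    daily_survival: 0.80
  - name: larva
    duration_days: 8
    daily_survival: 0.86
  - name: pupa
    duration_days: 1
    daily_survival: 0.90
  - name: adult
    duration_days: 14
    daily_survival: 0.93
fecundity_eggs_per_adult_per_day: 2
step_hours: 48
K_adult: 5692
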