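# Formulation / strength suffix vocabulary stripped from trade names.
# One term per line; '#' comments allowed. Editable: the two worked rules
# (strength numbers and formulation words) come from pharmacy schedules,
# where the same brand is listed per strength and dose form.
sr
cr
xr
xl
la
mr
ec
er
forte
retard
syrup
elixir
suspension
solution
injection
inj
tablets
tablet
capsules
capsule
drops
cream
ointment
gel
patch
spray
suppositories
paediatric
junior
infant
oral
iv
im
mg
mcg
ml
g
iu
plus
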