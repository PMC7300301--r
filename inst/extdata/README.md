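# Embedded reference physiology tables

These two CSV files define the reduced whole-body reference physiology used
by `build_reference_physiology()`.  They are compiled from widely published
reference values; they are deliberately small and auditable rather than a
copy of any proprietary physiology database.

## anthropometry.csv

One row per (age node, sex).  Values between nodes are obtained by monotone
piecewise-cubic interpolation on age.

| column     | units  | provenance                                                                 |
|------------|--------|----------------------------------------------------------------------------|
| age_y      | years  | table node (postnatal age)                                                  |
| bw_kg      | kg     | reference body mass: ICRP Publication 89 reference individuals (newborn 3.5 kg male, adult male 73 kg), WHO child-growth medians for intermediate infant ages |
| ht_cm      | cm     | ICRP 89 reference heights / WHO length-for-age medians                      |
| blood_ml   | ml     | total blood volume; ICRP 89 blood volumes (newborn ~80 ml/kg, adult male 5.3 L) |
| hct        | —      | hematocrit; neonatal value ~0.47 falling to ~0.35 during physiologic anemia of infancy, rising to adult 0.44 (male) / 0.40 (female) |
| co_l_min   | L/min  | cardiac output, ICRP 89 / pediatric reference ranges                        |
| ecw_scale  | —      | interstitial (extracellular water) expansion factor relative to the adult; reflects the higher extracellular-water fraction of infants (~25% of BW vs ~16% in adults) |

## organs.csv

One row per lumped organ of the reduced 9-organ graph (plus separate venous
and arterial plasma pools handled in code).  Fractions are age-independent;
age dependence enters through the age-resolved totals above.

| column           | meaning                                                             |
|------------------|---------------------------------------------------------------------|
| mass_frac_bw     | organ mass as fraction of body weight (adult reference composition) |
| vasc_frac_blood  | fraction of total blood volume residing in the organ vasculature (venous pool 0.18 and arterial pool 0.06 are set in code; all fractions sum to 1) |
| flow_frac_co     | organ plasma flow as fraction of cardiac plasma output; lung is in series and carries the total |
| lymph_frac_flow  | organ lymph flow as fraction of organ plasma flow (total adult lymph ~5-6 L/day) |
| int_frac_vol     | interstitial volume as fraction of organ volume (adult), multiplied by `ecw_scale` at younger ages |

Sources: ICRP Publication 89 (reference anatomy/physiology); WHO child
growth standards; standard whole-body PBPK compilations for organ flow and
lymph fractions (e.g. Shah & Betts, J Pharmacokinet Pharmacodyn 2012).
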