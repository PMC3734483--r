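# Seven-site exciton model of the Fenna-Matthews-Olson (FMO) monomer.
#
# Site energies (relative, cm^-1) and inter-site couplings (cm^-1) are the
# Chlorobaculum tepidum values of Adolphs & Renger, Biophys. J. 91, 2778
# (2006), as widely used in the exciton-transport literature (e.g.
# Mohseni et al., J. Chem. Phys. 129, 174106 (2008); Rebentrost et al.,
# New J. Phys. 11, 033003 (2009)).  Open-system rates are the standard
# choices from that literature: pure dephasing ~2.1 ps^-1 (room
# temperature), irreversible trapping from site 3 into the reaction
# centre at 1 ps^-1, and exciton recombination at 1 ns^-1 from every site.
#
# Energies/couplings are converted internally to angular frequencies via
# conversion_rad_per_time = 2*pi*c = 0.18836515673088532 rad ps^-1 per
# cm^-1, so all dynamical quantities below are in ps / ps^-1.
description: FMO 7-site exciton transport model (synthetic assembly from literature parameters)
energy_unit: cm^-1
time_unit: ps
conversion_rad_per_time: 0.18836515673088532
site_energies: [215.0, 220.0, 0.0, 125.0, 450.0, 330.0, 280.0]
couplings:
  - [1, 2, -104.1]
  - [1, 3, 5.1]
  - [1, 4, -4.3]
  - [1, 5, 4.7]
  - [1, 6, -15.1]
  - [1, 7, -7.8]
  - [2, 3, 32.6]
  - [2, 4, 7.1]
  - [2, 5, 5.4]
  - [2, 6, 8.3]
  - [2, 7, 0.8]
  - [3, 4, -46.8]
  - [3, 5, 1.0]
  - [3, 6, -8.1]
  - [3, 7, 5.1]
  - [4, 5, -70.7]
  - [4, 6, -14.7]
  - [4, 7, -61.5]
  - [5, 6, 89.7]
  - [5, 7, -2.5]
  - [6, 7, 32.7]
dephasing_rate: 2.1
trap:
  site: 3
  rate: 1.0
  label: RC
recombination_rate: 0.001
initial_site: 1
target: RC
# Edge subsets for phase optimization: the seven (A1) and three (A2)
# strongest couplings by magnitude.
edge_sets:
  A1:
    - [1, 2]
    - [5, 6]
    - [4, 5]
    - [4, 7]
    - [3, 4]
    - [6, 7]
    - [2, 3]
  A2:
    - [1, 2]
    - [5, 6]
    - [4, 5]
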