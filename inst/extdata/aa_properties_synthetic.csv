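# Synthetic stand-in amino-acid property table (AAindex-style literature
# scales; see package docs). 20 residue rows x 24 property columns, then a
# blank line and a group-definition section: group,<name>,<prop1>,<prop2>,<prop3>.
residue,hydrophobicity,hydrophilicity,mass,polarity,molecular_weight,melting_point,transfer_free_energy,buriability,bulkiness,solvation_free_energy,relative_mutability,residue_volume,volume,amino_acid_distribution,hydration_number,isoelectric_point,compressibility,chromatographic_index,unfolding_entropy_change,unfolding_enthalpy,unfolding_gibbs_free_energy_change,power_N_terminal_helix,power_C_terminal_helix,power_middle_helix
A,0.62,-0.5,15.0,8.1,89.1,297,0.3,0.38,11.50,0.67,100,88.6,31.0,8.25,1.5,6.00,-25.50,0.5,32.6,10.0,0.3,1.3,1.1,1.42
C,0.29,-1.0,47.0,5.5,121.2,178,0.9,0.47,13.46,0.38,20,108.5,55.0,1.37,1.0,5.07,-32.82,-6.8,37.0,14.5,3.5,0.8,0.9,0.70
D,-0.90,3.0,59.0,13.0,133.1,270,-0.6,0.15,11.68,-1.21,106,111.1,54.0,5.45,6.0,2.77,-33.12,-8.2,36.9,12.0,1.0,1.4,0.8,1.01
E,-0.74,3.0,73.0,12.3,147.1,249,-0.7,0.18,13.57,-2.02,102,138.4,83.0,6.75,7.0,3.22,-36.17,-16.9,40.7,13.5,1.4,1.3,0.9,1.51
F,1.19,-2.5,91.0,5.2,165.2,283,0.5,0.48,19.80,2.44,41,189.9,132.0,3.86,0.0,5.48,-34.54,13.2,47.0,18.5,4.5,0.9,1.1,1.13
G,0.48,0.0,1.0,9.0,75.1,290,0.3,0.37,3.40,0.00,49,60.1,3.0,7.07,1.0,5.97,-27.10,0.0,29.3,8.5,-0.2,1.1,1.6,0.57
H,-0.40,-0.5,82.0,10.4,155.2,277,-0.1,0.17,13.69,0.64,66,153.2,96.0,2.27,4.0,7.59,-31.84,-3.5,43.2,16.0,3.1,0.9,1.2,1.00
I,1.38,-1.8,57.0,5.2,131.2,284,0.7,0.60,21.40,1.92,96,166.7,111.0,5.96,1.0,6.02,-31.78,13.9,45.0,17.0,3.6,0.9,1.0,1.08
K,-1.50,3.0,73.0,11.3,146.2,224,-1.8,0.03,15.71,-0.57,56,168.6,119.0,5.84,4.5,9.74,-32.40,0.1,44.2,15.5,2.3,0.9,1.3,1.16
L,1.06,-1.8,57.0,4.9,131.2,293,0.5,0.45,21.40,1.22,40,166.7,111.0,9.66,1.0,5.98,-31.78,8.8,45.0,17.0,3.6,1.0,1.1,1.21
M,0.64,-1.3,75.0,5.7,149.2,281,0.4,0.40,16.25,1.02,94,162.9,105.0,2.42,1.0,5.74,-31.18,4.8,44.0,16.5,3.4,1.0,1.2,1.45
N,-0.78,0.2,58.0,11.6,132.1,236,-0.5,0.12,12.82,-0.60,134,114.1,56.0,4.06,2.0,5.41,-30.90,0.8,38.0,12.5,0.7,1.5,1.2,0.67
P,0.12,0.0,42.0,8.0,115.1,222,-0.3,0.18,17.43,0.14,56,112.7,32.5,4.70,3.0,6.30,-23.25,6.1,34.0,11.0,0.9,1.2,0.3,0.57
Q,-0.85,0.2,72.0,10.5,146.2,185,-0.7,0.07,14.45,-0.22,93,143.8,85.0,3.93,2.0,5.65,-32.60,-4.8,41.0,14.0,1.8,1.0,1.1,1.11
R,-2.53,3.0,101.0,10.5,174.2,238,-1.4,0.01,14.28,-2.10,65,173.4,124.0,5.53,3.0,10.76,-26.60,0.8,46.0,17.5,3.8,1.0,1.3,0.98
S,-0.18,0.3,31.0,9.2,105.1,228,-0.1,0.22,9.47,0.01,120,89.0,32.0,6.56,2.0,5.68,-29.88,1.2,33.0,10.5,0.6,1.4,0.9,0.77
T,-0.05,-0.4,45.0,8.6,119.1,253,-0.2,0.23,15.77,0.52,97,116.1,61.0,5.34,2.0,5.60,-31.23,2.7,36.0,12.0,1.3,1.2,0.8,0.83
V,1.08,-1.5,43.0,5.9,117.1,293,0.6,0.54,21.57,1.66,74,140.0,84.0,6.87,1.0,5.96,-30.62,2.7,41.0,15.0,2.8,0.9,0.9,1.06
W,0.81,-3.4,130.0,5.4,204.2,282,0.3,0.27,21.67,2.59,18,227.8,170.0,1.08,2.0,5.89,-30.24,14.9,52.0,21.0,5.4,1.0,1.2,1.08
Y,0.26,-2.3,107.0,6.2,181.2,344,-0.4,0.15,18.03,1.01,41,193.6,136.0,2.92,3.0,5.66,-35.01,6.1,48.0,19.0,4.7,0.9,1.1,0.69

group,A,hydrophobicity,hydrophilicity,mass
group,B,polarity,molecular_weight,melting_point
group,C,transfer_free_energy,buriability,bulkiness
group,D,solvation_free_energy,relative_mutability,residue_volume
group,E,volume,amino_acid_distribution,hydration_number
group,F,isoelectric_point,compressibility,chromatographic_index
group,G,unfolding_entropy_change,unfolding_enthalpy,unfolding_gibbs_free_energy_change
group,H,power_N_terminal_helix,power_C_terminal_helix,power_middle_helix
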