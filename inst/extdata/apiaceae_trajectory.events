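# Apiales chromosome-evolution trajectory, eudicot ancestor -> Apiaceae
# proto-chromosomes. SYNTHETIC TRANSCRIPTION: node chromosome counts
# (E 7, H 21, P 8, Q 10, R 11) and the named P1 = A5+A1+A2 fusion follow the
# published trajectory; the remaining fusion/crossover breakpoints are
# illustrative placements chosen to realise those counts. Satellites (S*)
# are the telomere-derived by-products of fusions; their loss drives the
# chromosome-number reductions.
NODE E
WGT
REN E1a A1
REN E2a A2
REN E3a A3
REN E4a A4
REN E5a A5
REN E6a A6
REN E7a A7
REN E1b B1
REN E2b B2
REN E3b B3
REN E4b B4
REN E5b B5
REN E6b B6
REN E7b B7
REN E1c C1
REN E2c C2
REN E3c C3
REN E4c C4
REN E5c C5
REN E6c C6
REN E7c C7
NODE H
# H -> P: 21 chromosomes fuse down to 8 before the Apiales WGD
EJ A5 A1 -> P1I +S1
LOSS S1
EJ P1I A2 -> P1 +S2
LOSS S2
EJ A3 B1 -> P2 +S3
LOSS S3
EJ A4 B2 -> P3I +S4
LOSS S4
EJ P3I B3 -> P3 +S5
LOSS S5
EJ A6 B4 -> P4 +S6
LOSS S6
NCF B6 B5@50 -> P5 +S7
LOSS S7
EJ B7 C1 -> P6I +S8
LOSS S8
EJ P6I C2 -> P6 +S9
LOSS S9
REN A7 P7
EJ C3 C4 -> P8I +S10
LOSS S10
EJ P8I C5 -> P8II +S11
LOSS S11
EJ P8II C6 -> P8III +S12
LOSS S12
EJ P8III C7 -> P8 +S13
LOSS S13
NODE P
WGD
# P -> Q: 16 post-WGD chromosomes reduce to 10 before the Apiaceae WGD
REN P1b Q1
EJ P7a P1a -> Q2 +S14
LOSS S14
EJ P3a P8a -> Q3 +S15
LOSS S15
REN P3b Q4
EJ P4a P5a -> Q5 +S16
LOSS S16
EJ P4b P6a -> Q6 +S17
LOSS S17
REN P5b Q7
EJ P6b P8b -> Q8 +S18
LOSS S18
EJ P2a P7b -> Q9 +S19
LOSS S19
REN P2b Q10
INV Q3 10..40
NODE Q
WGD
# Q -> R: 20 post-WGD chromosomes reduce to the 11 Apiaceae proto-chromosomes
X Q4a@40 Q7a@30 -> Q4I Q7I
REN Q1a R1
EJ Q1b Q2a -> R2 +S20
LOSS S20
EJ Q2b Q3a -> R3 +S21
LOSS S21
EJ Q4I Q3b -> R4 +S22
LOSS S22
EJ Q7I Q5a -> R5 +S23
LOSS S23
REN Q4b R6
EJ Q5b Q6a -> R7 +S24
LOSS S24
EJ Q6b Q7b -> R8 +S25
LOSS S25
EJ Q8a Q8b -> R9 +S26
LOSS S26
EJ Q9a Q10a -> R10 +S27
LOSS S27
EJ Q9b Q10b -> R11 +S28
LOSS S28
NODE R
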