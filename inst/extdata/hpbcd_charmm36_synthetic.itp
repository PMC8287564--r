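; Synthetic 2-HPbCD-like topology (heavy atoms + hydroxyl hydrogens).
; NOT the published charge set: charges are plausible CHARMM36-style
; values constructed for testing, neutral per subunit. Hydroxyl H
; charges are 0.42 e and hydroxyl epsilons match the original CHARMM36
; hydroxyl classes, so the ADD patch applies meaningfully.
[ moleculetype ]
; name  variant
HPBCD_SYN  original_charmm36

[ atomtypes ]
; type  sigma_nm  epsilon_kJmol
CG311      0.3564    0.335
CG321      0.3581    0.234
CG331      0.3669    0.326
OG301      0.2941    0.418
OGH        0.3154    0.804
OPH        0.3029    0.636
HGP        0.0400    0.192
HPH        0.0400    0.192

[ atoms ]
; nr  name  type  charge_e
   1  C1     CG311       0.3900
   2  O5     OG301      -0.2600
   3  C2     CG311       0.1400
   4  O2     OG301      -0.2000
   5  C3     CG311       0.1400
   6  O3     OGH        -0.6500
   7  HO3    HGP         0.4200
   8  C4     CG311       0.1400
   9  O4     OG301      -0.2000
  10  C5     CG311       0.1500
  11  C6     CG321       0.1300
  12  O6     OGH        -0.6500
  13  HO6    HGP         0.4200
  14  C7     CG321       0.1300
  15  C8     CG311       0.2000
  16  C9     CG331      -0.0700
  17  O8     OPH        -0.6500
  18  HO8    HPH         0.4200
  19  C1     CG311       0.3900
  20  O5     OG301      -0.2600
  21  C2     CG311       0.1400
  22  O2     OG301      -0.2000
  23  C3     CG311       0.1400
  24  O3     OGH        -0.6500
  25  HO3    HGP         0.4200
  26  C4     CG311       0.1400
  27  O4     OG301      -0.2000
  28  C5     CG311       0.1500
  29  C6     CG321       0.1300
  30  O6     OGH        -0.6500
  31  HO6    HGP         0.4200
  32  C7     CG321       0.1300
  33  C8     CG311       0.2000
  34  C9     CG331      -0.0700
  35  O8     OPH        -0.6500
  36  HO8    HPH         0.4200
  37  C1     CG311       0.3900
  38  O5     OG301      -0.2600
  39  C2     CG311       0.1400
  40  O2     OG301      -0.2000
  41  C3     CG311       0.1400
  42  O3     OGH        -0.6500
  43  HO3    HGP         0.4200
  44  C4     CG311       0.1400
  45  O4     OG301      -0.2000
  46  C5     CG311       0.1500
  47  C6     CG321       0.1300
  48  O6     OGH        -0.6500
  49  HO6    HGP         0.4200
  50  C7     CG321       0.1300
  51  C8     CG311       0.2000
  52  C9     CG331      -0.0700
  53  O8     OPH        -0.6500
  54  HO8    HPH         0.4200
  55  C1     CG311       0.3900
  56  O5     OG301      -0.2600
  57  C2     CG311       0.1400
  58  O2     OG301      -0.2000
  59  C3     CG311       0.1400
  60  O3     OGH        -0.6500
  61  HO3    HGP         0.4200
  62  C4     CG311       0.1400
  63  O4     OG301      -0.2000
  64  C5     CG311       0.1500
  65  C6     CG321       0.1300
  66  O6     OGH        -0.6500
  67  HO6    HGP         0.4200
  68  C7     CG321       0.1300
  69  C8     CG311       0.2000
  70  C9     CG331      -0.0700
  71  O8     OPH        -0.6500
  72  HO8    HPH         0.4200
  73  C1     CG311       0.3900
  74  O5     OG301      -0.2600
  75  C2     CG311       0.1400
  76  O2     OG301      -0.2000
  77  C3     CG311       0.1400
  78  O3     OGH        -0.6500
  79  HO3    HGP         0.4200
  80  C4     CG311       0.1400
  81  O4     OG301      -0.2000
  82  C5     CG311       0.1500
  83  C6     CG321       0.1300
  84  O6     OGH        -0.6500
  85  HO6    HGP         0.4200
  86  C7     CG321       0.1300
  87  C8     CG311       0.2000
  88  C9     CG331      -0.0700
  89  O8     OPH        -0.6500
  90  HO8    HPH         0.4200
  91  C1     CG311       0.3900
  92  O5     OG301      -0.2600
  93  C2     CG311       0.1400
  94  O2     OG301      -0.2000
  95  C3     CG311       0.1400
  96  O3     OGH        -0.6500
  97  HO3    HGP         0.4200
  98  C4     CG311       0.1400
  99  O4     OG301      -0.2000
 100  C5     CG311       0.1500
 101  C6     CG321       0.1300
 102  O6     OGH        -0.6500
 103  HO6    HGP         0.4200
 104  C7     CG321       0.1300
 105  C8     CG311       0.2000
 106  C9     CG331      -0.0700
 107  O8     OPH        -0.6500
 108  HO8    HPH         0.4200
 109  C1     CG311       0.3900
 110  O5     OG301      -0.2600
 111  C2     CG311       0.1400
 112  O2     OG301      -0.2000
 113  C3     CG311       0.1400
 114  O3     OGH        -0.6500
 115  HO3    HGP         0.4200
 116  C4     CG311       0.1400
 117  O4     OG301      -0.2000
 118  C5     CG311       0.1500
 119  C6     CG321       0.1300
 120  O6     OGH        -0.6500
 121  HO6    HGP         0.4200
 122  C7     CG321       0.1300
 123  C8     CG311       0.2000
 124  C9     CG331      -0.0700
 125  O8     OPH        -0.6500
 126  HO8    HPH         0.4200

[ tags ]
; name  group_tag
O3     glucopyranose_hydroxyl_O
O6     glucopyranose_hydroxyl_O
HO3    glucopyranose_hydroxyl_H
HO6    glucopyranose_hydroxyl_H
O8     hydroxypropyl_hydroxyl_O
HO8    hydroxypropyl_hydroxyl_H
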