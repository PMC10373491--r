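H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
     3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H GRAR740103
D Residue volume (Zamyatnin, 1972; Grantham, 1974)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    88.6   173.4   114.1   111.1   108.5   143.8   138.4    60.1   153.2   166.7
   166.7   168.6   162.9   189.9   112.7    89.0   116.1   227.8   193.6   140.0
//
H GRAR740102
D Polarity (Grantham, 1974)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     8.1    10.5    11.6    13.0     5.5    10.5    12.3     9.0    10.4     5.2
     4.9    11.3     5.7     5.2     8.0     9.2     8.6     5.4     6.2     5.9
//
H ZIMJ680104
D Isoelectric point (Zimmerman et al., 1968)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    6.00   10.76    5.41    2.77    5.05    5.65    3.22    5.97    7.59    6.02
    5.98    9.74    5.74    5.48    6.30    5.68    5.66    5.89    5.66    5.96
//
H BHAR880101
D Average flexibility indices (Bhaskaran-Ponnuswamy, 1988)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   0.357   0.529   0.463   0.511   0.346   0.493   0.497   0.544   0.323   0.462
   0.365   0.466   0.295   0.314   0.509   0.507   0.444   0.305   0.420   0.386
//
H ZIMJ680102
D Bulkiness (Zimmerman et al., 1968)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   11.50   14.28   12.82   11.68   13.46   14.45   13.57    3.40   13.69   21.40
   21.40   15.71   16.25   19.80   17.43    9.47   15.77   21.67   18.03   21.57
//
H HOPT810101
D Hydrophilicity value (Hopp-Woods, 1981)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -0.5     3.0     0.2     3.0    -1.0     0.2     3.0     0.0    -0.5    -1.8
    -1.8     3.0    -1.3    -2.5     0.0     0.3    -0.4    -3.4    -2.3    -1.5
//
H KLEP840101
D Net charge (Klein et al., 1984)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.0     1.0     0.0    -1.0     0.0     0.0    -1.0     0.0     0.0     0.0
     0.0     1.0     0.0     0.0     0.0     0.0     0.0     0.0     0.0     0.0
//
H FASG760101
D Molecular weight (Fasman, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   89.09  174.20  132.12  133.10  121.16  146.15  147.13   75.07  155.16  131.17
  131.17  146.19  149.21  165.19  115.13  105.09  119.12  204.23  181.19  117.15
//
H CHOP780201
D Normalized frequency of alpha-helix (Chou-Fasman, 1978)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.42    0.98    0.67    1.01    0.70    1.11    1.51    0.57    1.00    1.08
    1.21    1.16    1.45    1.13    0.57    0.77    0.83    1.08    0.69    1.06
//
H CHOP780202
D Normalized frequency of beta-sheet (Chou-Fasman, 1978)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.83    0.93    0.89    0.54    1.19    1.10    0.37    0.75    0.87    1.60
    1.30    0.74    1.05    1.38    0.55    0.75    1.19    1.37    1.47    1.70
//
H CHOP780203
D Normalized frequency of beta-turn (Chou-Fasman, 1978)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.66    0.95    1.56    1.46    1.19    0.98    0.74    1.56    0.95    0.47
    0.59    1.01    0.60    0.60    1.52    1.43    0.96    0.96    1.14    0.50
//
H CHOC760101
D Residue accessible surface area in tripeptide (Chothia, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   115.0   225.0   160.0   150.0   135.0   180.0   190.0    75.0   195.0   175.0
   170.0   200.0   185.0   210.0   145.0   115.0   140.0   255.0   230.0   155.0
//
H MCMT640101
D Refractivity (McMeekin et al., 1964)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    4.34   26.66   13.28   12.00   35.77   17.56   17.26    0.00   21.81   19.06
   18.78   21.29   21.64   29.40   10.93    6.35   11.01   42.53   31.53   13.92
//
H DAYM780201
D Relative mutability (Dayhoff et al., 1978)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   100.0    65.0   134.0   106.0    20.0    93.0   102.0    49.0    66.0    96.0
    40.0    56.0    94.0    41.0    56.0   120.0    97.0    18.0    41.0    74.0
//
H CHAM820101
D Polarizability parameter (Charton-Charton, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   0.046   0.291   0.134   0.105   0.128   0.180   0.151   0.000   0.230   0.186
   0.186   0.219   0.221   0.290   0.131   0.062   0.108   0.409   0.298   0.140
//
H SIDEHEAVY
D Side-chain heavy-atom count (curated)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.0     7.0     4.0     4.0     2.0     5.0     5.0     0.0     6.0     4.0
     4.0     5.0     4.0     7.0     3.0     2.0     3.0    10.0     8.0     3.0
//
H SIDEDONOR
D Side-chain hydrogen-bond donor count (curated)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.0     5.0     2.0     0.0     1.0     2.0     0.0     0.0     1.0     0.0
     0.0     3.0     0.0     0.0     0.0     1.0     1.0     1.0     1.0     0.0
//
H AROMATIC
D Aromatic side chain indicator (curated)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.0     0.0     0.0     0.0     0.0     0.0     0.0     0.0     1.0     0.0
     0.0     0.0     0.0     1.0     0.0     0.0     0.0     1.0     1.0     0.0
//
H ALIPHATIC
D Aliphatic side chain indicator (curated)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.0     0.0     0.0     0.0     0.0     0.0     0.0     0.0     0.0     1.0
     1.0     0.0     0.0     0.0     0.0     0.0     0.0     0.0     0.0     1.0
//
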