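country,1985/86,1989/90,1993/94,1997/98,2001/02,2005/06,2009/10,2013/14,2017/18
AM,,,,,,,28.73,18.97,22.89
AT,,37.83,47.3,39.57,28.82,41.25,37.3,22.85,23.86
BE-VLG,,,44.82,38.93,37.87,41.67,31.63,17.60,18.46
BE-WAL,54.01,40.95,45.87,45.95,30.91,37.85,26.4,17.02,16.17
BG,,,,,,45.42,,32.43,49.70
CA,,34.49,24.98,22.37,27.2,19.12,16.14,12.78,
CH,22.24,,,19.64,33.42,26.98,26.51,11.36,11.17
CZ,,,38.73,33.74,40.58,38.7,44.01,20.38,18.93
DE,,,29.45,29.78,37.05,25.1,25.24,17.93,
DK,,,41.82,48.13,50.39,38.61,26.75,20.39,25.27
EE,,,14.71,23.48,28.11,51.01,29.04,16.95,11.34
ES,,,25.78,,24.23,,22.97,10.79,
FI,10.59,12.28,17.13,12.43,12.68,11.54,7.06,7.68,
FR,,,40.1,33.58,19.95,24.44,28.25,18.25,
GB-ENG,,,,18.58,51.03,39.14,24.79,10.47,
GB-SCT,38.43,36.28,41.94,37.45,40.91,38.26,26.27,14.14,13.22
GB-WLS,51.57,51.92,52.94,54.48,47.98,45.9,31.48,13.45,13.95
GL,,,11.38,18.89,22.68,11.23,6.47,11.26,
GR,,,,52.09,39.94,42.74,43.1,28.59,
HR,,,,,34.31,44.63,43.27,34.26,29.22
HU,24.48,25.06,23.93,33.23,42.31,34.68,31.01,29.06,
IE,,,,29.26,14.97,17.96,13.6,5.11,6.52
IL,,,24.23,24.53,23.96,21.61,28.74,29.22,17.70
IS,,,,,,15.08,7.87,3.36,
IT,,,,,46.83,47.68,39.33,31.55,30.31
LT,,,15.67,18.12,27.63,25.47,24.41,13.65,9.01
LU,,,,,,29.23,23.44,12.58,
LV,,,18.64,29.41,19.78,31.03,26.68,9.46,6.77
MK,,,,,21.56,28.47,23.35,18.78,
MT,,,,,55.97,50,,31.85,26.13
NL,,,,,44.53,42.29,27.03,18.01,
NO,,8.47,9.95,17.05,16.71,21.41,10.99,4.06,6.85
PL,,10.13,22.51,20.68,19.19,18.63,17.31,12.77,
PT,,,,31.02,19.3,20.85,12.4,11.27,
RO,,,,,,33.07,34.58,28.57,
RU,,,21.39,27.61,31.83,42.4,12.85,12.16,6.03
SE,14.34,27.55,21.76,21.29,18.73,15.35,10.63,5.08,7.53
SI,,,,,33.02,58.58,54.43,25.14,20.11
SK,,,33.78,33.33,,41.97,28.19,19.73,20.35
UA,,,,,43,59.24,45.44,17.45,
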