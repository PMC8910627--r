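country,1985/86,1989/90,1993/94,1997/98,2001/02,2005/06,2009/10,2013/14,2017/18
AM,,,,,,,11.61,6.68,5.48
AT,,18.64,29.09,23.96,22.59,34.94,28.29,11.25,18.42
BE-VLG,,,25.86,22.31,24.44,24.12,15.79,10.74,7.94
BE-WAL,36.73,26.93,28.77,28.24,20.11,20.78,19.1,9.58,8.45
BG,,,,,,33.37,,17.65,35.09
CA,,25.16,19.39,17.29,18.84,15.62,13.77,8.20,
CH,9.86,,,9.18,14.65,15.93,13.08,6.32,3.81
CZ,,,18.61,19.93,29.61,26.59,33.51,13.89,11.86
DE,,,20.35,22.72,24.27,15.21,13.83,7.42,
DK,,,35.01,38.56,39.91,28.3,17.72,12.52,17.81
EE,,,5.18,11.48,12.04,41.16,24.56,11.89,6.31
ES,,,24.52,,18.36,,22.78,8.21,
FI,9.76,6.95,9.58,8.56,8.45,7.17,6.81,3.33,
FR,,,17.82,16.01,10.47,13.31,15.38,8.95,
GB-ENG,,,,27.75,43.72,37.82,17.6,9.20,
GB-SCT,27.34,29.17,33.43,33.81,41.49,36.54,24.75,11.90,12.32
GB-WLS,40.95,41.59,46.17,36.9,31.45,42.61,28.12,10.97,12.42
GL,,,10.61,15.1,7.14,13.27,8.47,2.58,
GR,,,,31,21.64,25.79,34.47,17.61,
HR,,,,,20.79,29.75,26.68,13.86,14.31
HU,9.73,5.62,14.57,11.63,20.75,23.25,19.76,18.23,
IE,,,,12.37,11.78,18.78,9.7,3.51,5.03
IL,,,11.42,8.56,11.49,9.77,9.63,9.76,6.60
IS,,,,,,10.93,4.62,2.09,
IT,,,,,29.48,30.58,26.36,17.02,17.61
LT,,,6.76,10.5,13.01,20.04,16.81,6.01,7.12
LU,,,,,,17.75,14.51,7.78,
LV,,,5.56,12.57,12.62,25.07,21.08,4.02,5.43
MK,,,,,7.28,14.76,12.64,9.09,
MT,,,,,42.51,39.02,,26.48,18.70
NL,,,,,24.47,28.51,17.21,12.89,
NO,,8.03,7.08,13.46,17.19,21.19,9.57,3.56,2.74
PL,,2.95,9.56,8.09,7.83,12.87,10.71,9.27,
PT,,,,8.97,13.45,9.57,6.42,4.24,
RO,,,,,,10.7,8.37,9.38,
RU,,,10.51,24.51,18.43,36.12,9.29,5.64,2.07
SE,11.61,18.16,12.4,13.53,11.89,11.13,7.58,3.08,5.15
SI,,,,,19.92,33.61,41.78,18.27,14.17
SK,,,10.83,17.13,,27.29,15.94,11.19,10.39
UA,,,,,20.49,46.47,29.93,10.16,
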