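decade,location,planted,germinated
1770,3,1,0
1780,2,24,0
1790,2,3,0
1790,10,2,0
1800,2,18,0
1800,10,4,0
1810,1,2,0
1810,2,28,0
1810,10,2,0
1820,2,18,0
1820,10,18,0
1830,1,1,0
1830,2,39,0
1830,10,17,0
1840,1,12,0
1840,2,36,2
1840,4,5,0
1840,10,78,3
1850,1,1,0
1850,2,17,0
1850,3,5,0
1850,10,25,0
1860,1,23,0
1860,2,49,0
1860,3,8,0
1860,4,11,0
1860,10,34,0
1870,1,330,0
1870,2,128,0
1870,3,8,0
1870,10,2,0
1880,1,502,1
1880,2,58,0
1880,4,32,0
1880,10,3,0
1890,1,356,0
1890,2,157,1
1890,3,13,0
1900,1,587,11
1900,2,179,8
1900,7,216,1
1900,10,6,0
1910,1,132,0
1910,2,248,0
1910,4,11,1
1910,7,144,1
1910,10,13,0
1920,1,164,2
1920,2,519,15
1920,4,31,2
1920,10,15,0
1930,1,48,0
1930,2,159,8
1930,3,3,0
1930,4,33,2
1930,5,2,1
1930,7,144,10
1930,8,1,0
1930,10,4,0
1940,1,424,10
1940,2,111,6
1940,3,2,0
1940,7,117,3
1940,10,10,1
1950,1,261,44
1950,2,156,2
1950,3,9,1
1950,4,41,0
1950,7,60,0
1950,10,38,4
1960,1,109,41
1960,2,95,2
1960,3,19,1
1960,7,44,0
1960,10,44,3
1970,1,257,60
1970,2,134,2
1970,3,29,5
1970,4,12,0
1970,7,258,26
1970,8,2,0
1970,9,2,0
1970,10,74,3
1980,1,31,4
1980,2,125,2
1980,3,7,2
1980,4,11,4
1980,5,2,1
1980,6,3,1
1980,7,231,42
1980,10,97,10
1990,1,141,12
1990,2,125,11
1990,3,27,7
1990,4,14,1
1990,6,8,0
1990,7,270,44
1990,8,2,1
1990,9,21,5
1990,10,116,19
2000,1,214,65
2000,2,126,7
2000,3,22,6
2000,6,7,0
2000,7,276,116
2000,8,5,0
2000,10,219,50
2010,2,144,14
2010,3,37,11
2010,7,419,141
2010,10,98,24
2010,Greenhouse,62,7
2020,1,49,13
2020,2,175,44
2020,3,18,7
2020,7,324,118
2020,10,125,9
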