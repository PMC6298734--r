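"area","year","nonempty_PH","nonempty_ATF"
"Shumagin",1990,15,18
"Shumagin",1993,50,21
"Shumagin",1996,31,138
"Shumagin",1999,3,25
"Shumagin",2001,98,85
"Shumagin",2003,26,49
"Shumagin",2005,13,11
"Shumagin",2007,55,44
"Shumagin",2009,37,55
"Shumagin",2011,43,56
"Shumagin",2013,103,79
"Chirikof",1990,28,106
"Chirikof",1993,42,87
"Chirikof",1996,22,219
"Chirikof",1999,0,58
"Chirikof",2001,79,135
"Chirikof",2003,31,44
"Chirikof",2005,7,16
"Chirikof",2007,16,35
"Chirikof",2009,44,43
"Chirikof",2011,36,43
"Chirikof",2013,96,57
"Kodiak",1990,39,143
"Kodiak",1993,22,111
"Kodiak",1996,30,244
"Kodiak",1999,37,94
"Kodiak",2001,75,280
"Kodiak",2003,9,42
"Kodiak",2005,1,26
"Kodiak",2007,58,34
"Kodiak",2009,40,74
"Kodiak",2011,48,97
"Kodiak",2013,102,124
"Yakutat",1990,2,14
"Yakutat",1993,9,28
"Yakutat",1996,0,1
"Yakutat",1999,0,0
"Yakutat",2001,0,0
"Yakutat",2003,3,10
"Yakutat",2005,7,15
"Yakutat",2007,17,19
"Yakutat",2009,14,39
"Yakutat",2011,17,23
"Yakutat",2013,35,39
"Southeastern",1990,0,0
"Southeastern",1993,0,0
"Southeastern",1996,0,0
"Southeastern",1999,0,0
"Southeastern",2001,0,0
"Southeastern",2003,0,5
"Southeastern",2005,4,12
"Southeastern",2007,11,15
"Southeastern",2009,10,25
"Southeastern",2011,7,13
"Southeastern",2013,16,14
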