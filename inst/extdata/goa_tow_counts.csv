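"area","year","total_tows","positive_PH","positive_ATF"
"Shumagin",1990,5,5,4
"Shumagin",1993,166,144,142
"Shumagin",1996,169,124,148
"Shumagin",1999,143,118,137
"Shumagin",2001,136,111,103
"Shumagin",2003,229,186,208
"Shumagin",2005,176,142,170
"Shumagin",2007,205,172,190
"Shumagin",2009,196,169,180
"Shumagin",2011,162,146,153
"Shumagin",2013,136,115,116
"Shumagin",2015,182,136,158
"Shumagin",2017,124,104,114
"Chirikof",1990,25,16,18
"Chirikof",1993,168,98,144
"Chirikof",1996,168,100,142
"Chirikof",1999,161,79,142
"Chirikof",2001,133,75,108
"Chirikof",2003,170,107,139
"Chirikof",2005,174,103,150
"Chirikof",2007,196,138,152
"Chirikof",2009,186,134,163
"Chirikof",2011,155,109,137
"Chirikof",2013,126,94,107
"Chirikof",2015,175,133,144
"Chirikof",2017,118,77,106
"Kodiak",1990,78,32,62
"Kodiak",1993,210,124,183
"Kodiak",1996,186,68,167
"Kodiak",1999,242,112,202
"Kodiak",2001,189,86,157
"Kodiak",2003,242,137,203
"Kodiak",2005,287,146,258
"Kodiak",2007,257,151,213
"Kodiak",2009,275,145,241
"Kodiak",2011,226,145,204
"Kodiak",2013,187,114,162
"Kodiak",2015,252,193,221
"Kodiak",2017,178,115,166
"Yakutat",1990,117,35,57
"Yakutat",1993,117,46,98
"Yakutat",1996,105,27,98
"Yakutat",1999,132,53,115
"Yakutat",2001,0,0,0
"Yakutat",2003,76,26,70
"Yakutat",2005,90,29,80
"Yakutat",2007,57,21,50
"Yakutat",2009,83,37,77
"Yakutat",2011,68,25,64
"Yakutat",2013,61,25,58
"Yakutat",2015,80,37,78
"Yakutat",2017,70,29,63
"Southeastern",1990,61,2,23
"Southeastern",1993,65,4,27
"Southeastern",1996,88,25,72
"Southeastern",1999,64,15,50
"Southeastern",2001,0,0,0
"Southeastern",2003,78,22,64
"Southeastern",2005,92,31,77
"Southeastern",2007,64,20,53
"Southeastern",2009,72,19,64
"Southeastern",2011,54,22,45
"Southeastern",2013,38,9,34
"Southeastern",2015,66,25,54
"Southeastern",2017,45,17,37
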