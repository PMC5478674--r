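"year","season","precip_mm"
2000,"DJF",175.854589840188
2000,"MAM",92.1453252948671
2000,"JJA",13.4939070081463
2000,"SON",83.6113013961477
2001,"DJF",146.729450668426
2001,"MAM",106.908619178796
2001,"JJA",6.82116712088381
2001,"SON",99.761547623804
2002,"DJF",160.164842501012
2002,"MAM",115.546114700513
2002,"JJA",15.0775522910829
2002,"SON",77.8012615109892
2003,"DJF",154.988949680841
2003,"MAM",90.6900782223224
2003,"JJA",0
2003,"SON",76.104504305229
2004,"DJF",165.804994127619
2004,"MAM",109.650543778315
2004,"JJA",35.396653140649
2004,"SON",79.9136629141521
2005,"DJF",187.250675314451
2005,"MAM",85.4120412843648
2005,"JJA",2.01160453856417
2005,"SON",101.09482403067
2006,"DJF",176.36224212321
2006,"MAM",73.3740855099677
2006,"JJA",20.2937475731523
2006,"SON",90.680837079649
2007,"DJF",171.621170872629
2007,"MAM",90.4084998501805
2007,"JJA",37.7876775785684
2007,"SON",63.3957564969227
2008,"DJF",180.178185423894
2008,"MAM",100.0311768053
2008,"JJA",24.5672799561975
2008,"SON",106.252371192286
2009,"DJF",164.467604607788
2009,"MAM",104.390501424815
2009,"JJA",31.5696520975392
2009,"SON",70.0363384346892
2010,"DJF",140.602041034434
2010,"MAM",103.806867817227
2010,"JJA",0
2010,"SON",100.464943687551
2011,"DJF",152.794011757915
2011,"MAM",90.071114754393
2011,"JJA",0
2011,"SON",86.9952191509212
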