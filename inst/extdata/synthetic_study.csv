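mouse,group,day,tv
C1,C,0,166.14506432168147
C1,C,4,279.8147486305892
C1,C,7,354.4721851140768
C1,C,10,451.65645373359814
C1,C,14,719.1268140814253
C1,C,18,1086.0510575252952
C1,C,21,1453.8450814302466
C2,C,0,188.2403085619448
C2,C,4,274.01666353413117
C2,C,7,348.28940255813126
C2,C,10,566.5317284073881
C2,C,14,818.1646401392394
C2,C,18,1254.5402914184347
C2,C,21,1811.741111932406
C3,C,0,241.6021417965214
C3,C,4,360.7900190128536
C3,C,7,472.8612208996209
C3,C,10,579.1088721315322
C3,C,14,992.0715320838905
C3,C,18,1442.0822226046507
C3,C,21,1948.362164105009
C4,C,0,149.65506054216868
C4,C,4,230.89998941864965
C4,C,7,286.82502120980803
C4,C,10,392.82191065673004
C4,C,14,565.6057294543594
C4,C,18,779.2634977634174
C4,C,21,1092.707161709419
C5,C,0,191.64069306986454
C5,C,4,279.6920554144516
C5,C,7,359.0588544383598
C5,C,10,480.6918869447291
C5,C,14,748.1864401464697
C5,C,18,1102.7326859988393
C5,C,21,1393.3382698882745
C6,C,0,177.15406160066811
C6,C,4,253.73239809437646
C6,C,7,360.83872996825755
C6,C,10,476.63895864943504
C6,C,14,678.2778753736347
C6,C,18,1064.7749199597176
C6,C,21,1338.7248602163668
A1,A,0,255.7358570266218
A1,A,4,334.81420314416704
A1,A,7,455.6503363778634
A1,A,10,552.218738739294
A1,A,14,848.9957381969655
A1,A,18,1017.6869071892452
A1,A,21,1325.0345284380444
A2,A,0,199.07710939901963
A2,A,4,231.2133370497228
A2,A,7,328.2805558924438
A2,A,10,370.6490359734093
A2,A,14,526.1359663349424
A2,A,18,620.1991877823838
A2,A,21,704.6984630408955
A3,A,0,207.88289801874484
A3,A,4,287.08717644189926
A3,A,7,332.6918780873641
A3,A,10,408.95469820979326
A3,A,14,524.6981757091858
A3,A,18,648.8406065427766
A3,A,21,780.8612321895415
A4,A,0,176.9306060630876
A4,A,4,262.1771431848494
A4,A,7,321.0224192273348
A4,A,10,413.04592893127995
A4,A,14,514.1842951971012
A4,A,18,708.8748779752923
A4,A,21,874.8683275713337
A5,A,0,186.65934667260694
A5,A,4,243.28966302520905
A5,A,7,315.6286772213976
A5,A,10,372.0885252556439
A5,A,14,452.7566551272657
A5,A,18,625.4666845187041
A5,A,21,751.381418949017
A6,A,0,178.94160076525048
A6,A,4,219.4617205925569
A6,A,7,279.6259995954769
A6,A,10,324.293825491345
A6,A,14,470.8378508987001
A6,A,18,574.6464483799218
A6,A,21,700.8234261951845
B1,B,0,204.99899996621508
B1,B,4,288.24414066334066
B1,B,7,406.49750391815746
B1,B,10,469.8918056156323
B1,B,14,669.6575032123242
B1,B,18,924.8145008059191
B1,B,21,1190.712967689349
B2,B,0,183.93165955691885
B2,B,4,246.33783717488194
B2,B,7,340.5568164872116
B2,B,10,397.0766382517533
B2,B,14,541.5586879502836
B2,B,18,740.2520392621099
B2,B,21,971.714286983647
B3,B,0,186.80310161035433
B3,B,4,256.2012604920815
B3,B,7,326.59270600462264
B3,B,10,395.35737510723516
B3,B,14,563.3202569289967
B3,B,18,684.9819326482359
B3,B,21,938.393209895236
B4,B,0,140.8944616021558
B4,B,4,187.66224134265798
B4,B,7,240.8131212325265
B4,B,10,273.3534409340597
B4,B,14,427.577749306378
B4,B,18,497.14500571891887
B4,B,21,657.5832623845523
B5,B,0,174.5246625184714
B5,B,4,209.03299883640904
B5,B,7,242.31615018769452
B5,B,10,294.55448286106946
B5,B,14,434.3793496359757
B5,B,18,563.6285830919004
B5,B,21,687.0149305647464
B6,B,0,154.60824570332034
B6,B,4,224.5237608799983
B6,B,7,253.3853055803951
B6,B,10,298.4933877396124
B6,B,14,459.785312999221
B6,B,18,559.9660588146095
B6,B,21,662.9392189099508
AB1,AB,0,234.4797357991218
AB1,AB,4,284.55292287398163
AB1,AB,7,261.6675725016666
AB1,AB,10,256.6757508854104
AB1,AB,14,288.3287097688253
AB1,AB,18,309.19770408180267
AB1,AB,21,357.17112299168224
AB2,AB,0,199.49769790748988
AB2,AB,4,205.76581778832863
AB2,AB,7,215.83975691787097
AB2,AB,10,232.40658473442107
AB2,AB,14,258.9531201493508
AB2,AB,18,256.7320225858628
AB2,AB,21,267.7068224032563
AB3,AB,0,155.37619646522552
AB3,AB,4,150.76218989067488
AB3,AB,7,173.4305483467071
AB3,AB,10,174.591374927158
AB3,AB,14,199.90225543938013
AB3,AB,18,188.76601722638856
AB3,AB,21,199.92886839628605
AB4,AB,0,166.56720077335797
AB4,AB,4,162.3787145350975
AB4,AB,7,179.72947475596123
AB4,AB,10,166.15903783108382
AB4,AB,14,172.80621462737042
AB4,AB,18,201.91532742835955
AB4,AB,21,182.80382148216816
AB5,AB,0,217.18846534539958
AB5,AB,4,237.91656860055087
AB5,AB,7,241.5777996418479
AB5,AB,10,224.01264848116162
AB5,AB,14,208.756215313926
AB5,AB,18,272.4603232597012
AB5,AB,21,253.74986163979392
AB6,AB,0,223.94894189155679
AB6,AB,4,224.11435250047458
AB6,AB,7,236.8096985970523
AB6,AB,10,233.23737253694998
AB6,AB,14,229.98663377768554
AB6,AB,18,267.8389987751976
AB6,AB,21,282.2599058863793
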