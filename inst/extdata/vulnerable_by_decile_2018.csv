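"country","decile","count"
"Afghanistan",1,281586
"Algeria",5,74397
"Angola",2,3652123
"Argentina",6,78462
"Armenia",7,27064
"Azerbaijan",6,116150
"Bangladesh",4,359780
"Belize",5,14532
"Benin",1,97491
"Bhutan",4,114385
"Bolivia",4,1307831
"Botswana",4,323599
"Brazil",5,4107300
"Brazil",6,2296
"Brazil",7,619
"Brunei",8,9630
"Burkina Faso",1,699570
"Burundi",1,10597
"Cambodia",3,43972
"Cameroon",2,1279030
"Central African Republic",1,1081841
"Chad",1,5814
"China",4,167314
"China",5,6787216
"China",6,6793121
"China",7,11323668
"China",8,8414197
"China",9,14142
"Colombia",6,6277835
"Congo (Brazzaville)",2,521800
"Costa Rica",7,138011
"Cote d'Ivoire",1,379448
"Democratic Republic of the Congo",1,22586819
"Djibouti",2,73050
"Ecuador",5,552572
"Egypt",5,37780
"Equatorial Guinea",4,242345
"Eritrea",1,905464
"Ethiopia",1,10422734
"Gabon",3,499707
"Georgia",6,111973
"Ghana",3,354713
"Greece",9,7327
"Guatemala",4,533186
"Guinea",1,427253
"Guinea-Bissau",1,120745
"Guyana",4,138904
"Honduras",4,58882
"India",2,231656
"India",3,1488560
"India",4,4623346
"India",6,276547
"Indonesia",3,10454226
"Iran",7,341174
"Iraq",4,49668
"Japan",9,38825
"Japan",10,6288
"Jordan",7,91671
"Kazakhstan",7,2494396
"Kenya",3,1825765
"Kyrgyzstan",5,495765
"Laos",3,18010
"Liberia",2,664940
"Malawi",2,133687
"Malaysia",6,1790903
"Mali",2,2373844
"Mauritania",3,5129
"Mexico",5,229259
"Mexico",6,384600
"Mexico",7,275250
"Morocco",5,93028
"Mozambique",1,3206555
"Myanmar",3,2544010
"Namibia",3,752476
"Nepal",3,2665443
"Nicaragua",5,73046
"Niger",1,1545113
"Nigeria",3,2067928
"Oman",8,84388
"Pakistan",3,4425880
"Panama",6,137946
"Paraguay",5,227331
"Peru",6,2674949
"Philippines",4,1517133
"Russia",8,1205085
"Rwanda",3,32081
"Saudi Arabia",8,2392280
"Senegal",2,467056
"Sierra Leone",1,154596
"Somalia",1,2140834
"South Africa",4,289322
"South Sudan",1,601410
"Sri Lanka",7,62951
"Sudan",4,542183
"Suriname",4,94635
"Swaziland",3,226
"Syria",6,48738
"Tajikistan",4,301870
"Tanzania",2,4950775
"Thailand",7,77295
"The Gambia",2,3245
"Togo",2,14488
"Trinidad and Tobago",6,6520
"Turkey",7,48653
"Uganda",2,371059
"Ukraine",8,4956
"USA",9,4728
"Uzbekistan",5,805059
"Venezuela",6,3346588
"Vietnam",5,175519
"Yemen",3,3017147
"Zambia",1,2125572
"Zimbabwe",2,936801
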