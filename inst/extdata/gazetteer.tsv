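France	country
Paris	capital
Germany	country
Berlin	capital
Spain	country
Madrid	capital
Italy	country
Rome	capital
Japan	country
Tokyo	capital
China	country
Beijing	capital
India	country
New Delhi	capital
Brazil	country
Brasilia	capital
Mexico	country
Mexico City	capital
Egypt	country
Cairo	capital
Kenya	country
Nairobi	capital
Nigeria	country
Abuja	capital
Russia	country
Moscow	capital
Ukraine	country
Kyiv	capital
Poland	country
Warsaw	capital
Sweden	country
Stockholm	capital
Norway	country
Oslo	capital
Finland	country
Helsinki	capital
Portugal	country
Lisbon	capital
Greece	country
Athens	capital
Turkey	country
Ankara	capital
Ireland	country
Dublin	capital
Iceland	country
Reykjavik	capital
Austria	country
Vienna	capital
Hungary	country
Budapest	capital
Netherlands	country
Amsterdam	capital
Belgium	country
Brussels	capital
Switzerland	country
Bern	capital
Argentina	country
Buenos Aires	capital
Chile	country
Santiago	capital
Peru	country
Lima	capital
Cuba	country
Havana	capital
Morocco	country
Rabat	capital
Ethiopia	country
Addis Ababa	capital
Ghana	country
Accra	capital
Thailand	country
Bangkok	capital
Vietnam	country
Hanoi	capital
Indonesia	country
Jakarta	capital
Australia	country
Canberra	capital
New Zealand	country
Wellington	capital
South Korea	country
Seoul	capital
Liberia	country
Monrovia	capital
Eritrea	country
Asmara	capital
Abkhazia	country
Canada	country
Ottawa	capital
United States	country
Washington	capital
Illinois	us_place
Springfield	us_place
Chicago	us_place
California	us_place
Sacramento	us_place
Los Angeles	us_place
Texas	us_place
Austin	us_place
Houston	us_place
New York	us_place
Albany	us_place
Florida	us_place
Tallahassee	us_place
Miami	us_place
Ohio	us_place
Columbus	us_place
Cleveland	us_place
Michigan	us_place
Lansing	us_place
Detroit	us_place
Colorado	us_place
Denver	us_place
Arizona	us_place
Phoenix	us_place
Georgia	us_place
Atlanta	us_place
Massachusetts	us_place
Boston	us_place
Oregon	us_place
Salem	us_place
Portland	us_place
Nevada	us_place
Carson City	us_place
Las Vegas	us_place
Minnesota	us_place
Saint Paul	us_place
Minneapolis	us_place
Pennsylvania	us_place
Harrisburg	us_place
Philadelphia	us_place
Montana	us_place
Helena	us_place
Billings	us_place
Utah	us_place
Salt Lake City	us_place
Ontario	ca_place
Toronto	ca_place
Mississauga	ca_place
Quebec	ca_place
Quebec City	ca_place
Montreal	ca_place
British Columbia	ca_place
Vancouver	ca_place
Whistler	ca_place
Alberta	ca_place
Edmonton	ca_place
Calgary	ca_place
Banff	ca_place
Jasper	ca_place
Manitoba	ca_place
Winnipeg	ca_place
Saskatchewan	ca_place
Regina	ca_place
Saskatoon	ca_place
Nova Scotia	ca_place
Halifax	ca_place
New Brunswick	ca_place
Fredericton	ca_place
Moncton	ca_place
Prince Edward Island	ca_place
Charlottetown	ca_place
Yukon	ca_place
Whitehorse	ca_place
Northwest Territories	ca_place
Yellowknife	ca_place
Nunavut	ca_place
Iqaluit	ca_place
Niagara Falls	ca_place
Victoria	ca_place
Munich	world_city
Barcelona	world_city
Milan	world_city
Marseille	world_city
Osaka	world_city
Shanghai	world_city
Mumbai	world_city
Sao Paulo	world_city
Casablanca	world_city
Lagos	world_city
Cape Town	world_city
Johannesburg	world_city
Sydney	world_city
Melbourne	world_city
Auckland	world_city
Geneva	world_city
Zurich	world_city
Hamburg	world_city
Frankfurt	world_city
Rotterdam	world_city
Antwerp	world_city
Porto	world_city
Valencia	world_city
Seville	world_city
Naples	world_city
Turin	world_city
Krakow	world_city
Gothenburg	world_city
Bergen	world_city
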